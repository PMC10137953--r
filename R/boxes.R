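# Bounding boxes live in data frames with 0-based, half-open pixel
# coordinates: a box spans columns [x_min, x_max) and rows [y_min, y_max).

BOX_COLUMNS <- c("frame", "x_min", "y_min", "x_max", "y_max",
                 "label", "confidence", "provenance")

#' Construct a detection / annotation data frame
#'
#' The package represents per-frame boxes for a whole video as one data
#' frame with a 0-based `frame` column; frames with no rows simply have no
#' boxes. Coordinates are 0-based half-open corners.
#'
#' @param frame integer 0-based frame indices.
#' @param x_min,y_min,x_max,y_max box corners in pixels; `x_min < x_max`,
#'   `y_min < y_max`.
#' @param label class name, default `"polyp"`.
#' @param confidence detection score in `[0, 1]`; 1 for ground truth.
#' @param provenance one of `"detector"`, `"propagated"`, `"ground_truth"`.
#' @return data frame with columns
#'   `frame, x_min, y_min, x_max, y_max, label, confidence, provenance`.
#' @examples
#' boxes_df(frame = 0L, x_min = 10, y_min = 10, x_max = 50, y_max = 40)
#' @export
boxes_df <- function(frame = integer(), x_min = numeric(), y_min = numeric(),
                     x_max = numeric(), y_max = numeric(), label = "polyp",
                     confidence = 1, provenance = "detector") {
  n <- max(length(frame), length(x_min), length(y_min),
           length(x_max), length(y_max))
  df <- data.frame(
    frame = as.integer(rep_len(frame, n)),
    x_min = as.numeric(rep_len(x_min, n)), y_min = as.numeric(rep_len(y_min, n)),
    x_max = as.numeric(rep_len(x_max, n)), y_max = as.numeric(rep_len(y_max, n)),
    label = rep_len(as.character(label), n),
    confidence = rep_len(as.numeric(confidence), n),
    provenance = rep_len(as.character(provenance), n),
    stringsAsFactors = FALSE
  )
  validate_boxes(df)
}

validate_boxes <- function(df, allow_empty = TRUE) {
  if (!is.data.frame(df)) stop("boxes must be a data frame", call. = FALSE)
  missing_cols <- setdiff(BOX_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("boxes data frame is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    if (!allow_empty) stop("boxes data frame is empty", call. = FALSE)
    return(df)
  }
  bad <- df$x_min >= df$x_max | df$y_min >= df$y_max
  if (any(bad)) {
    stop("malformed box at row(s) ", paste(which(bad), collapse = ", "),
         ": need x_min < x_max and y_min < y_max", call. = FALSE)
  }
  if (any(df$confidence < 0 | df$confidence > 1)) {
    stop("box confidence must lie in [0, 1]", call. = FALSE)
  }
  if (any(df$frame < 0L)) stop("frame indices must be >= 0", call. = FALSE)
  df
}

empty_boxes <- function() boxes_df()

#' Clip boxes to a rectangular region
#'
#' Intersects each box with `[x_lim[1], x_lim[2]) x [y_lim[1], y_lim[2])`;
#' boxes whose intersection has zero area are dropped.
#'
#' @param boxes a [boxes_df()] data frame.
#' @param x_lim,y_lim length-2 numeric bounds.
#' @return clipped data frame.
#' @export
clip_boxes <- function(boxes, x_lim, y_lim) {
  boxes <- validate_boxes(boxes)
  if (nrow(boxes) == 0L) return(boxes)
  boxes$x_min <- pmax(boxes$x_min, x_lim[1L])
  boxes$y_min <- pmax(boxes$y_min, y_lim[1L])
  boxes$x_max <- pmin(boxes$x_max, x_lim[2L])
  boxes$y_max <- pmin(boxes$y_max, y_lim[2L])
  keep <- boxes$x_min < boxes$x_max & boxes$y_min < boxes$y_max
  boxes[keep, , drop = FALSE]
}

# scale-then-translate affine remap of box corners
remap_boxes <- function(boxes, scale, dx, dy) {
  if (nrow(boxes) == 0L) return(boxes)
  boxes$x_min <- boxes$x_min * scale + dx
  boxes$x_max <- boxes$x_max * scale + dx
  boxes$y_min <- boxes$y_min * scale + dy
  boxes$y_max <- boxes$y_max * scale + dy
  boxes
}

# positive-area overlap of one box against a set; returns logical per row of b
overlaps_any <- function(x_min, y_min, x_max, y_max, b) {
  if (nrow(b) == 0L) return(FALSE)
  iw <- pmin(x_max, b$x_max) - pmax(x_min, b$x_min)
  ih <- pmin(y_max, b$y_max) - pmax(y_min, b$y_min)
  any(iw > 0 & ih > 0)
}
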