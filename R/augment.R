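# Mosaic and mixup augmentation with bounding-box remapping.
#
# Mosaic: four annotated images are each letterboxed to the output size
# (aspect preserved, mid-gray 114/255 pad), then laid out around a randomly
# chosen center point — first image top-left, then top-right, bottom-left,
# bottom-right — and the composite is cropped to the canvas. Every box is
# remapped by its tile's scale and offset and clipped to the tile's
# quadrant; boxes reduced to zero area are dropped.
#
# Mixup: the second image gets mild photometric jitter, a small random
# translation and an optional horizontal flip, and is then blended 1:1 with
# the first; box labels are the union of both sets (the second transformed
# accordingly).

#' Annotated image
#'
#' Pairs pixels with their box annotations.
#'
#' @param image numeric `[H, W]` or `[H, W, C]` array in `[0, 1]`.
#' @param boxes a [boxes_df()] data frame (the `frame` column is unused
#'   here and conventionally 0).
#' @return list of class `annotated_image` with elements `image`, `boxes`.
#' @export
annotated_image <- function(image, boxes = boxes_df()) {
  check_image(image)
  boxes <- validate_boxes(boxes)
  d <- dim(image)
  if (nrow(boxes) > 0L &&
      any(boxes$x_max > d[2L] | boxes$y_max > d[1L])) {
    stop("boxes extend beyond the image bounds", call. = FALSE)
  }
  structure(list(image = image, boxes = boxes), class = "annotated_image")
}

#' @export
print.annotated_image <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<annotated_image> %d x %d, %d channel(s), %d box(es)\n",
              d[1L], d[2L], if (length(d) == 3L) d[3L] else 1L,
              nrow(x$boxes)))
  invisible(x)
}

#' Mosaic augmentation of four annotated images
#'
#' @param images list of exactly four [annotated_image()] objects (or lists
#'   with `image` and `boxes`).
#' @param size output canvas side in pixels (default 640).
#' @param center optional `c(x, y)` composite center, strictly inside the
#'   canvas; by default sampled uniformly from the middle half
#'   `[0.25 size, 0.75 size]` of each axis.
#' @param seed optional integer seed; the same seed reproduces the output
#'   exactly.
#' @return an [annotated_image()] of side `size`.
#' @export
augment_mosaic <- function(images, size = 640L, center = NULL, seed = NULL) {
  if (!is.list(images) || length(images) != 4L) {
    stop("mosaic requires exactly four annotated images, got ",
         length(images), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(center)) {
    center <- stats::runif(2L, 0.25 * size, 0.75 * size)
  }
  cx <- center[1L]; cy <- center[2L]
  if (cx <= 0 || cx >= size || cy <= 0 || cy >= size) {
    stop("'center' must lie strictly inside the canvas", call. = FALSE)
  }

  nchan <- max(vapply(images, function(a) {
    d <- dim(a$image); if (length(d) == 3L) d[3L] else 1L
  }, integer(1L)))
  canvas <- array(114 / 255, dim = c(size, size, nchan))

  # tile offsets: the k-th letterboxed image is placed so that the corner
  # adjacent to the center coincides with it
  offsets <- list(c(cx - size, cy - size),  # top-left
                  c(cx, cy - size),         # top-right
                  c(cx - size, cy),         # bottom-left
                  c(cx, cy))                # bottom-right
  quadrants <- list(list(x = c(0, cx), y = c(0, cy)),
                    list(x = c(cx, size), y = c(0, cy)),
                    list(x = c(0, cx), y = c(cy, size)),
                    list(x = c(cx, size), y = c(cy, size)))

  out_boxes <- list()
  for (k in 1:4) {
    a <- images[[k]]
    lb <- letterbox_resize(a$image, size = size)
    tile <- lb$image
    if (length(dim(tile)) == 2L) {
      tile <- array(rep(tile, nchan), dim = c(size, size, nchan))
    }
    off <- offsets[[k]]
    q <- quadrants[[k]]
    # integer pixel ranges of the quadrant on the canvas
    x0 <- ceiling(q$x[1L]); x1 <- floor(q$x[2L])
    y0 <- ceiling(q$y[1L]); y1 <- floor(q$y[2L])
    if (x1 > x0 && y1 > y0) {
      dst_cols <- (x0 + 1L):x1
      dst_rows <- (y0 + 1L):y1
      src_cols <- dst_cols - round(off[1L])
      src_rows <- dst_rows - round(off[2L])
      canvas[dst_rows, dst_cols, ] <- tile[src_rows, src_cols, , drop = FALSE]
    }
    b <- validate_boxes(a$boxes)
    b <- remap_boxes(b, lb$scale, lb$pad_x + off[1L], lb$pad_y + off[2L])
    b <- clip_boxes(b, x_lim = q$x, y_lim = q$y)
    out_boxes[[k]] <- b
  }

  boxes <- do.call(rbind, out_boxes)
  rownames(boxes) <- NULL
  if (nchan == 1L) canvas <- canvas[, , 1L]
  annotated_image(clamp01(canvas), boxes)
}

#' Mixup augmentation of two annotated images
#'
#' Applies random photometric jitter (brightness/contrast within
#' `1 +- jitter`), a random translation of up to `shift` of the image size,
#' and a horizontal flip with probability `flip_prob` to image `b`, then
#' blends `0.5 a + 0.5 b'` pixel-wise. Output boxes are the union of `a`'s
#' boxes and `b`'s transformed boxes.
#'
#' @param a,b [annotated_image()] objects of identical dimensions (bring
#'   them to a common size first; a mismatch is an error).
#' @param jitter brightness/contrast jitter fraction (default 0.1).
#' @param shift maximum translation as a fraction of each axis
#'   (default 0.05).
#' @param flip_prob probability of a horizontal flip of `b` (default 0.5).
#' @param seed optional integer seed for reproducibility.
#' @return an [annotated_image()].
#' @export
augment_mixup <- function(a, b, jitter = 0.1, shift = 0.05, flip_prob = 0.5,
                          seed = NULL) {
  check_image(a$image); check_image(b$image)
  if (!identical(dim(a$image), dim(b$image))) {
    stop("images must have identical dimensions after preprocessing (got ",
         paste(dim(a$image), collapse = "x"), " vs ",
         paste(dim(b$image), collapse = "x"), ")", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  d <- dim(a$image)
  h <- d[1L]; w <- d[2L]

  img_b <- b$image
  boxes_b <- validate_boxes(b$boxes)

  # photometric jitter: contrast then brightness
  if (jitter > 0) {
    contrast <- stats::runif(1L, 1 - jitter, 1 + jitter)
    brightness <- stats::runif(1L, -jitter, jitter)
    img_b <- clamp01(img_b * contrast + brightness)
  }
  # horizontal flip (x' = W - x)
  if (flip_prob > 0 && stats::runif(1L) < flip_prob) {
    img_b <- flip_horizontal(img_b)
    if (nrow(boxes_b) > 0L) {
      new_min <- w - boxes_b$x_max
      boxes_b$x_max <- w - boxes_b$x_min
      boxes_b$x_min <- new_min
    }
  }
  # translation jitter, whole pixels, pad with mid-gray
  if (shift > 0) {
    dx <- round(stats::runif(1L, -shift, shift) * w)
    dy <- round(stats::runif(1L, -shift, shift) * h)
    img_b <- translate_image(img_b, dx, dy, fill = 114 / 255)
    boxes_b <- clip_boxes(remap_boxes(boxes_b, 1, dx, dy),
                          x_lim = c(0, w), y_lim = c(0, h))
  }

  mixed <- 0.5 * a$image + 0.5 * img_b
  boxes <- rbind(validate_boxes(a$boxes), boxes_b)
  rownames(boxes) <- NULL
  annotated_image(mixed, boxes)
}

flip_horizontal <- function(image) {
  if (length(dim(image)) == 2L) {
    image[, rev(seq_len(ncol(image)))]
  } else {
    image[, rev(seq_len(dim(image)[2L])), , drop = FALSE]
  }
}

translate_image <- function(image, dx, dy, fill = 0) {
  d <- dim(image)
  h <- d[1L]; w <- d[2L]
  was_2d <- length(d) == 2L
  if (was_2d) image <- array(image, dim = c(h, w, 1L))
  out <- array(fill, dim = dim(image))
  src_rows <- seq_len(h) - dy
  src_cols <- seq_len(w) - dx
  ok_r <- src_rows >= 1L & src_rows <= h
  ok_c <- src_cols >= 1L & src_cols <= w
  if (any(ok_r) && any(ok_c)) {
    out[which(ok_r), which(ok_c), ] <-
      image[src_rows[ok_r], src_cols[ok_c], , drop = FALSE]
  }
  if (was_2d) out <- out[, , 1L]
  out
}
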