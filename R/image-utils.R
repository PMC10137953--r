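# Shared raster helpers. Images are numeric arrays [H, W] or [H, W, C],
# values in [0, 1].

#' Convert an image to luminance
#'
#' RGB images are reduced with ITU-R BT.601 luma weights
#' (0.299 R + 0.587 G + 0.114 B); grayscale matrices pass through unchanged.
#'
#' @param image numeric matrix `[H, W]` or array `[H, W, C]` with C >= 3
#'   (alpha, if present, is ignored).
#' @return numeric matrix `[H, W]`.
#' @export
as_gray <- function(image) {
  if (is.matrix(image)) return(image)
  if (!is.array(image) || length(dim(image)) != 3L) {
    stop("'image' must be a 2-D matrix or 3-D array", call. = FALSE)
  }
  if (dim(image)[3L] < 3L) return(image[, , 1L])
  0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L]
}

#' Bilinear image resize
#'
#' @param image numeric matrix or `[H, W, C]` array.
#' @param height,width target extents in pixels.
#' @return resized plain array with the same number of channels.
#' @export
resize_image <- function(image, height, width) {
  check_image(image)
  # EBImage indexes dim 1 as x; for [H, W] arrays that means w = height.
  out <- EBImage::resize(image, w = height, h = width, filter = "bilinear")
  out <- as.array(out)
  dimnames(out) <- NULL
  out
}

#' Aspect-preserving resize with letterbox padding
#'
#' Scales the image by `min(size / W, size / H)`, anchors it at the top-left
#' corner of a `size` x `size` canvas and fills the remaining band with a
#' constant pad value (mid-gray 114/255 by default).
#'
#' @param image numeric matrix or `[H, W, C]` array.
#' @param size canvas side in pixels.
#' @param pad_value fill value for the letterbox band, in `[0, 1]`.
#' @return list with `image` (the padded canvas), `scale` (the factor applied
#'   to both axes) and `pad_x`, `pad_y` (offsets of the image on the canvas,
#'   always 0 with top-left anchoring; kept explicit for box remapping).
#' @export
letterbox_resize <- function(image, size = 640L, pad_value = 114 / 255) {
  check_image(image)
  d <- dim(image)
  h <- d[1L]; w <- d[2L]
  scale <- min(size / w, size / h)
  new_h <- max(1L, round(h * scale))
  new_w <- max(1L, round(w * scale))
  resized <- resize_image(image, new_h, new_w)
  nchan <- if (length(d) == 3L) d[3L] else 1L
  canvas <- array(pad_value, dim = c(size, size, nchan))
  canvas[seq_len(new_h), seq_len(new_w), ] <-
    if (nchan == 1L) resized else resized
  if (nchan == 1L) canvas <- canvas[, , 1L]
  list(image = canvas, scale = scale, pad_x = 0L, pad_y = 0L)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

check_image <- function(image) {
  if (!is.numeric(image) || is.null(dim(image)) ||
      !(length(dim(image)) %in% c(2L, 3L))) {
    stop("'image' must be a numeric 2-D matrix or 3-D array", call. = FALSE)
  }
  if (any(dim(image)[1:2] < 1L)) {
    stop("'image' must have positive height and width", call. = FALSE)
  }
  invisible(image)
}
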