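# 64-bit DCT perceptual hash. Dialect, fixed for reproducibility:
# grayscale (BT.601) -> bilinear resize to 32x32 -> orthonormal 2-D type-II
# DCT -> top-left 8x8 block (DC included) -> bit = 1 iff coefficient
# strictly exceeds the median of those 64 values. Strict inequality makes a
# constant image hash to all zeros. Because the DC term participates in the
# median split, the hash is NOT invariant to adding a constant to all pixels.

PHASH_BITS <- 64L

#' Perceptual-hash fingerprint of an image
#'
#' Computes the classic DCT perceptual hash: the image is converted to
#' luminance, resized to `resize_to` x `resize_to`, transformed with an
#' orthonormal 2-D type-II DCT, and the top-left `hash_size` x `hash_size`
#' coefficient block (DC included) is thresholded against its own median
#' (bit = 1 iff coefficient > median, so ties give 0). Bits are ordered
#' row-major over the coefficient block.
#'
#' Near-duplicate frames produce fingerprints at small Hamming distance;
#' frames at distance 9 or more are conventionally no longer considered
#' similar (see [phash_similar()]).
#'
#' @param image numeric matrix `[H, W]` or array `[H, W, C]`, values in
#'   `[0, 1]` (any positive range works; the hash only depends on relative
#'   coefficient order).
#' @param hash_size side of the retained DCT block; the fingerprint has
#'   `hash_size^2` bits (default 8, i.e. 64 bits).
#' @param resize_to side of the DCT working image (default 32).
#' @return a `fingerprint` object: an integer vector of 0/1 bits with a hex
#'   representation via [format()] / [as.character()].
#' @examples
#' img <- matrix(runif(64 * 64), 64, 64)
#' fp <- phash_fingerprint(img)
#' format(fp)
#' phash_distance(fp, fp)
#' @export
phash_fingerprint <- function(image, hash_size = 8L, resize_to = 32L) {
  check_image(image)
  g <- as_gray(image)
  if (!all(dim(g) == c(resize_to, resize_to))) {
    g <- resize_image(g, resize_to, resize_to)
  }
  M <- dct_matrix(resize_to)
  coef <- M %*% g %*% t(M)
  block <- coef[seq_len(hash_size), seq_len(hash_size), drop = FALSE]
  vals <- as.vector(t(block))  # row-major over the block
  # round before the median split so coefficients that are mathematically
  # equal (typically exact zeros of structured images) are not ordered by
  # floating-point summation noise; genuine coefficient gaps are far
  # coarser than 1e-10
  vals <- round(vals, 10L)
  bits <- as.integer(vals > stats::median(vals))
  new_fingerprint(bits)
}

#' Hamming distance between two fingerprints
#'
#' Number of bit positions at which the fingerprints differ. Lower means
#' more similar; 0 means identical hashes.
#'
#' @param a,b `fingerprint` objects of equal length.
#' @return integer in `[0, 64]` for the default 64-bit hash.
#' @export
phash_distance <- function(a, b) {
  a <- as_fingerprint(a)
  b <- as_fingerprint(b)
  if (length(a) != length(b)) {
    stop("fingerprints have different lengths (", length(a), " vs ",
         length(b), ")", call. = FALSE)
  }
  sum(unclass(a) != unclass(b))
}

#' Are two frames similar under the Hamming threshold?
#'
#' Frames are similar iff their fingerprint Hamming distance is *strictly
#' below* the threshold; at a distance of 9 or more (default threshold 9)
#' they are no longer considered similar.
#'
#' @param d non-negative integer Hamming distance.
#' @param threshold non-negative integer cut-off (default 9).
#' @return logical.
#' @export
phash_similar <- function(d, threshold = 9L) {
  stopifnot(is.numeric(d), d >= 0, is.numeric(threshold), threshold >= 0)
  d < threshold
}

new_fingerprint <- function(bits) {
  bits <- as.integer(bits)
  if (anyNA(bits) || !all(bits %in% c(0L, 1L))) {
    stop("fingerprint bits must be 0/1", call. = FALSE)
  }
  structure(bits, class = "fingerprint")
}

as_fingerprint <- function(x) {
  if (inherits(x, "fingerprint")) return(x)
  new_fingerprint(x)
}

#' @export
format.fingerprint <- function(x, ...) {
  bits <- unclass(x)
  if (length(bits) %% 4L != 0L) return(paste(bits, collapse = ""))
  nib <- matrix(bits, nrow = 4L)
  paste(sprintf("%x", as.integer(crossprod(nib, c(8L, 4L, 2L, 1L)))),
        collapse = "")
}

#' @export
as.character.fingerprint <- function(x, ...) format(x)

#' @export
print.fingerprint <- function(x, ...) {
  cat("<fingerprint> ", format(x), " (", sum(unclass(x)), "/", length(x),
      " bits set)\n", sep = "")
  invisible(x)
}

# Orthonormal type-II DCT matrix: M[k+1, n+1] = a_k cos(pi (2n+1) k / (2N)),
# a_0 = sqrt(1/N), a_k = sqrt(2/N). Cached per size.
dct_matrix <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    k <- 0:(n - 1L)
    M <- sqrt(2 / n) * cos(outer(k, k, function(k, j) pi * (2 * j + 1) * k / (2 * n)))
    M[1L, ] <- sqrt(1 / n)
    cache[[key]] <<- M
    M
  }
})
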