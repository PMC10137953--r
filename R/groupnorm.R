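#' Group normalization of a feature tensor
#'
#' Normalizes a 4-D activation tensor indexed `(N, C, H, W)` over channel
#' groups within each sample: the channels of each sample are split into
#' `groups` contiguous groups of `C / groups` channels, and every value is
#' standardized by the mean and (population) standard deviation of its own
#' group, taken over all channels in the group and all spatial positions.
#' An optional per-channel affine transform `gamma * x_hat + beta` follows.
#'
#' Unlike batch normalization, the statistics never mix samples: the result
#' for one sample is identical whether it is normalized alone or inside a
#' batch. `groups = 1` reproduces layer normalization per sample;
#' `groups = C` reproduces instance normalization.
#'
#' @param x numeric 4-D array with dimensions `(N, C, H, W)`.
#' @param groups number of channel groups `G`; `C` must be divisible by `G`
#'   (default 32).
#' @param eps small positive stabilizer added to the variance (default 1e-5).
#' @param gamma,beta per-channel affine parameters, length `C`; defaults 1
#'   and 0 (pure normalization).
#' @return array of the same shape as `x`.
#' @examples
#' x <- array(rnorm(2 * 4 * 3 * 3), dim = c(2, 4, 3, 3))
#' y <- group_normalize(x, groups = 2)
#' mean(y[1, 1:2, , ])  # ~0 per sample/group
#' @export
group_normalize <- function(x, groups = 32L, eps = 1e-5,
                            gamma = NULL, beta = NULL) {
  if (!is.array(x) || length(dim(x)) != 4L) {
    stop("'x' must be a 4-D array with dimensions (N, C, H, W)", call. = FALSE)
  }
  d <- dim(x)
  if (any(d < 1L)) stop("all tensor extents must be positive", call. = FALSE)
  n_batch <- d[1L]; n_chan <- d[2L]
  groups <- as.integer(groups)
  if (groups < 1L || n_chan %% groups != 0L) {
    stop("channel count C = ", n_chan, " is not divisible by groups G = ",
         groups, call. = FALSE)
  }
  if (!is.numeric(eps) || eps <= 0) stop("'eps' must be > 0", call. = FALSE)
  if (is.null(gamma)) gamma <- rep(1, n_chan)
  if (is.null(beta)) beta <- rep(0, n_chan)
  if (length(gamma) != n_chan || length(beta) != n_chan) {
    stop("'gamma' and 'beta' must have length C = ", n_chan, call. = FALSE)
  }

  cpg <- n_chan %/% groups
  out <- x
  for (n in seq_len(n_batch)) {
    for (g in seq_len(groups)) {
      ch <- ((g - 1L) * cpg + 1L):(g * cpg)
      v <- x[n, ch, , , drop = FALSE]
      mu <- mean(v)
      sigma2 <- mean((v - mu)^2)
      out[n, ch, , ] <- (v - mu) / sqrt(sigma2 + eps)
    }
  }
  # per-channel affine
  for (c in seq_len(n_chan)) {
    out[, c, , ] <- gamma[c] * out[, c, , ] + beta[c]
  }
  out
}
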