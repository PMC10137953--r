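# Independent oracles used to cross-check the implementation. Each is
# written directly from the defining formula or stated rule, avoiding the
# code paths it checks.

# Brute-force 64-bit DCT hash of an already 32x32 grayscale image: direct
# double-sum type-II DCT per coefficient, then the median split.
oracle_phash_bits <- function(img32) {
  N <- nrow(img32)
  n <- 0:(N - 1L)
  vals <- numeric(64L)
  idx <- 1L
  for (k1 in 0:7) {
    for (k2 in 0:7) {
      acc <- 0
      c2 <- cos(pi * (2 * n + 1) * k2 / (2 * N))
      for (n1 in n) {
        acc <- acc + sum(img32[n1 + 1L, ] * cos(pi * (2 * n1 + 1) * k1 / (2 * N)) * c2)
      }
      a1 <- if (k1 == 0) sqrt(1 / N) else sqrt(2 / N)
      a2 <- if (k2 == 0) sqrt(1 / N) else sqrt(2 / N)
      vals[idx] <- a1 * a2 * acc
      idx <- idx + 1L
    }
  }
  vals <- round(vals, 10L)
  as.integer(vals > stats::median(vals))
}

# Direct-arithmetic metric oracle (fractions of 100)
oracle_metrics <- function(tp, fp, tn, fn) {
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  acc <- if (tp + fp + tn + fn > 0) 100 * (tp + tn) / (tp + fp + tn + fn) else NA_real_
  prec <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(sens) && !is.na(spec) && sens + spec > 0)
    2 * sens * spec / (sens + spec) else NA_real_
  c(sensitivity = sens, specificity = spec, accuracy = acc,
    precision = prec, f1 = f1)
}

# Rule-level propagation oracle. flags: logical, frame holds a counted
# detector box; dists: consecutive-frame Hamming distances (length n - 1).
# Returns logical: which frames receive a propagated box. Works from the
# maximal runs of the flag sequence, so propagated frames never extend a
# run.
oracle_vafa_filled <- function(flags, dists, run_length = 5L, threshold = 9L) {
  n <- length(flags)
  filled <- rep(FALSE, n)
  r <- rle(flags)
  ends <- cumsum(r$lengths)
  for (k in seq_along(r$lengths)) {
    if (!r$values[k] || r$lengths[k] < run_length) next
    j <- ends[k] + 1L
    while (j <= n && !flags[j] && dists[j - 1L] < threshold) {
      filled[j] <- TRUE
      j <- j + 1L
    }
  }
  filled
}

# Fingerprint sequence with exact consecutive Hamming distances; plain 0/1
# vectors (phash_distance coerces them).
fingerprints_with_distances <- function(dists) {
  n <- length(dists) + 1L
  fps <- vector("list", n)
  bits <- rep(0L, 64L)
  fps[[1L]] <- bits
  ptr <- 0L
  for (t in seq_along(dists)) {
    d <- dists[t]
    stopifnot(d <= 64L)
    if (d > 0L) {
      pos <- ((ptr + 0:(d - 1L)) %% 64L) + 1L
      bits[pos] <- 1L - bits[pos]
      ptr <- (ptr + d) %% 64L
    }
    fps[[t + 1L]] <- bits
  }
  fps
}

# Detections data frame from a flag vector: one unit box per flagged frame
flags_to_detections <- function(flags, confidence = 0.9) {
  idx <- which(flags) - 1L
  if (length(idx) == 0L) return(polypstab::boxes_df())
  polypstab::boxes_df(frame = idx, x_min = 10, y_min = 10, x_max = 50,
                      y_max = 50, confidence = confidence)
}

# Direct layer / instance normalization (population variance), for the
# G = 1 / G = C equivalences
oracle_layer_norm <- function(x, eps) {
  out <- x
  for (n in seq_len(dim(x)[1L])) {
    v <- x[n, , , , drop = FALSE]
    out[n, , , ] <- (v - mean(v)) / sqrt(mean((v - mean(v))^2) + eps)
  }
  out
}

oracle_instance_norm <- function(x, eps) {
  out <- x
  for (n in seq_len(dim(x)[1L])) {
    for (c in seq_len(dim(x)[2L])) {
      v <- x[n, c, , , drop = FALSE]
      out[n, c, , ] <- (v - mean(v)) / sqrt(mean((v - mean(v))^2) + eps)
    }
  }
  out
}
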