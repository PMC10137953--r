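# Synthetic hysteroscopy-like video plus a flickering-detector simulator.
# The scene is a reddish low-frequency noise background (a smooth random
# field cropped with a per-frame drifting offset, so consecutive-frame
# similarity is controllable) with zero or one bright soft-edged elliptical
# lesion drifting across it. Ground truth is the axis-aligned bounding box
# of the ellipse in every frame. The simulated detector reproduces the
# failure modes the stabilizer targets: per-frame dropout, localization
# jitter and spurious boxes.

#' Synthetic scene configuration
#'
#' Defaults describe a short desk-scale clip: 50 frames of 128 x 128 px,
#' one bright ellipse of radii 18 x 12 px drifting ~0.6 px/frame over a
#' slowly moving background. `change_magnitude` scales *all* temporal
#' variation (background drift and lesion drift): 0 yields a static video
#' whose frames are pixel-identical, 1 the default gentle motion; larger
#' values push consecutive-frame fingerprint distances up.
#'
#' @param n_frames number of frames (>= 1).
#' @param frame_size frame side in pixels.
#' @param has_polyp does the video contain a lesion?
#' @param polyp_center starting `c(x, y)` of the ellipse center; default is
#'   the frame center.
#' @param polyp_drift per-frame `c(dx, dy)` drift of the center, pixels.
#' @param polyp_radii `c(rx, ry)` ellipse radii, pixels.
#' @param change_magnitude scale on all inter-frame change (>= 0).
#' @param bg_drift per-frame background shift in pixels at
#'   `change_magnitude = 1`.
#' @param noise_scale size of one background blob in pixels (larger =
#'   smoother background).
#' @param seed integer RNG seed; identical configs reproduce identical
#'   videos.
#' @return list of class `synth_scene_config`.
#' @export
synth_scene_config <- function(n_frames = 50L, frame_size = 128L,
                               has_polyp = TRUE, polyp_center = NULL,
                               polyp_drift = c(0.5, 0.3),
                               polyp_radii = c(18, 12),
                               change_magnitude = 1,
                               bg_drift = 1.5,
                               noise_scale = 16L,
                               seed = 1L) {
  if (is.null(polyp_center)) polyp_center <- c(frame_size, frame_size) / 2
  stopifnot(n_frames >= 1L, frame_size >= 8L, change_magnitude >= 0,
            all(polyp_radii > 0), noise_scale >= 2L)
  structure(list(n_frames = as.integer(n_frames),
                 frame_size = as.integer(frame_size),
                 has_polyp = isTRUE(has_polyp),
                 polyp_center = as.numeric(polyp_center),
                 polyp_drift = as.numeric(polyp_drift),
                 polyp_radii = as.numeric(polyp_radii),
                 change_magnitude = as.numeric(change_magnitude),
                 bg_drift = as.numeric(bg_drift),
                 noise_scale = as.integer(noise_scale),
                 seed = as.integer(seed)),
            class = "synth_scene_config")
}

#' Generate a synthetic hysteroscopy-like video
#'
#' @param config a [synth_scene_config()].
#' @return list of class `synth_video` with `frames` (list of
#'   `[H, W, 3]` arrays in `[0, 1]`), `gt` (a [boxes_df()] of ground-truth
#'   boxes, provenance `"ground_truth"`), `n_frames`, `frame_size` and the
#'   `config`.
#' @examples
#' vid <- synth_video(synth_scene_config(n_frames = 5, frame_size = 64))
#' vid$gt
#' @export
synth_video <- function(config = synth_scene_config()) {
  stopifnot(inherits(config, "synth_scene_config"))
  set.seed(config$seed)
  s <- config$frame_size
  n <- config$n_frames
  cm <- config$change_magnitude

  # smooth background field, larger than the frame so crops can drift
  max_shift <- ceiling(cm * config$bg_drift * n) + 2L
  field_size <- s + max_shift
  coarse <- matrix(stats::runif((field_size %/% config$noise_scale + 2L)^2,
                                0.25, 0.75),
                   field_size %/% config$noise_scale + 2L)
  field <- resize_image(coarse, field_size, field_size)

  centers <- matrix(NA_real_, n, 2L)
  if (config$has_polyp) {
    for (t in seq_len(n)) {
      centers[t, ] <- config$polyp_center + cm * config$polyp_drift * (t - 1L)
    }
    rx <- config$polyp_radii[1L]; ry <- config$polyp_radii[2L]
    if (any(centers[, 1L] + rx <= 0 | centers[, 1L] - rx >= s |
            centers[, 2L] + ry <= 0 | centers[, 2L] - ry >= s)) {
      stop("degenerate geometry: the lesion drifts fully off-canvas; ",
           "reduce drift or n_frames", call. = FALSE)
    }
  }

  xs <- matrix(rep(seq_len(s) - 0.5, each = s), s)        # column coord x
  ys <- matrix(rep(seq_len(s) - 0.5, times = s), s)       # row coord y
  frames <- vector("list", n)
  gt <- vector("list", n)
  for (t in seq_len(n)) {
    shift <- round(cm * config$bg_drift * (t - 1L))
    base <- field[(1L + shift):(s + shift), (1L + shift):(s + shift)]
    if (config$has_polyp) {
      cx <- centers[t, 1L]; cy <- centers[t, 2L]
      rx <- config$polyp_radii[1L]; ry <- config$polyp_radii[2L]
      d2 <- ((xs - cx) / rx)^2 + ((ys - cy) / ry)^2
      lesion <- 0.45 * stats::plogis((1 - d2) * 6)  # soft-edged ellipse
      base <- base + lesion
      gt[[t]] <- boxes_df(frame = t - 1L,
                          x_min = max(0, cx - rx), y_min = max(0, cy - ry),
                          x_max = min(s, cx + rx), y_max = min(s, cy + ry),
                          label = "polyp", confidence = 1,
                          provenance = "ground_truth")
    } else {
      gt[[t]] <- empty_boxes()
    }
    base <- clamp01(base)
    # reddish tint: mucosa-like dominance of the red channel
    frames[[t]] <- array(c(base, 0.55 * base, 0.45 * base), dim = c(s, s, 3L))
  }

  gt <- do.call(rbind, gt)
  rownames(gt) <- NULL
  structure(list(frames = frames, gt = gt, n_frames = n, frame_size = s,
                 config = config),
            class = "synth_video")
}

#' @export
print.synth_video <- function(x, ...) {
  cat(sprintf("<synth_video> %d frames, %d x %d px, %s, %d gt box(es)\n",
              x$n_frames, x$frame_size, x$frame_size,
              if (x$config$has_polyp) "with polyp" else "polyp-free",
              nrow(x$gt)))
  invisible(x)
}

#' Flickering-detector configuration
#'
#' Defaults emulate a usable but unstable single-frame detector: it drops a
#' visible lesion in 20% of frames, perturbs box edges by up to 2 px, and
#' hallucinates a spurious box in about 5% of frames. True-box confidences
#' are drawn from `conf_range`, spurious ones from `fp_conf_range` (which
#' deliberately straddles the 0.4 working threshold).
#'
#' @param miss_probability per-frame probability that a ground-truth box is
#'   not emitted.
#' @param localization_jitter maximum absolute perturbation of each box
#'   edge, pixels.
#' @param false_positive_rate expected number of spurious boxes per frame
#'   (Poisson).
#' @param conf_range,fp_conf_range uniform confidence ranges for true and
#'   spurious boxes.
#' @param seed integer RNG seed.
#' @return list of class `detector_sim_config`.
#' @export
detector_sim_config <- function(miss_probability = 0.2,
                                localization_jitter = 2,
                                false_positive_rate = 0.05,
                                conf_range = c(0.45, 0.95),
                                fp_conf_range = c(0.05, 0.9),
                                seed = 1L) {
  stopifnot(miss_probability >= 0, miss_probability <= 1,
            localization_jitter >= 0, false_positive_rate >= 0)
  structure(list(miss_probability = miss_probability,
                 localization_jitter = localization_jitter,
                 false_positive_rate = false_positive_rate,
                 conf_range = as.numeric(conf_range),
                 fp_conf_range = as.numeric(fp_conf_range),
                 seed = as.integer(seed)),
            class = "detector_sim_config")
}

#' Simulate flickering detector output from ground truth
#'
#' Each ground-truth box is emitted with probability
#' `1 - miss_probability`, each edge independently perturbed by up to
#' `localization_jitter` pixels (geometry kept valid and on-canvas), with a
#' confidence drawn from `conf_range`. Spurious boxes are added per frame
#' with Poisson rate `false_positive_rate` at uniform positions.
#'
#' @param gt [boxes_df()] ground truth for the video.
#' @param n_frames total number of frames.
#' @param frame_size frame side in pixels (for placing/clipping boxes).
#' @param config a [detector_sim_config()].
#' @return [boxes_df()] of simulated detections, provenance `"detector"`.
#' @export
simulate_detector <- function(gt, n_frames, frame_size,
                              config = detector_sim_config()) {
  gt <- validate_boxes(gt)
  stopifnot(inherits(config, "detector_sim_config"))
  set.seed(config$seed)
  out <- list()

  if (nrow(gt) > 0L) {
    emitted <- stats::runif(nrow(gt)) >= config$miss_probability
    for (i in which(emitted)) {
      j <- config$localization_jitter
      xm <- gt$x_min[i] + stats::runif(1L, -j, j)
      ym <- gt$y_min[i] + stats::runif(1L, -j, j)
      xM <- gt$x_max[i] + stats::runif(1L, -j, j)
      yM <- gt$y_max[i] + stats::runif(1L, -j, j)
      xm <- max(0, min(xm, frame_size - 1)); ym <- max(0, min(ym, frame_size - 1))
      xM <- min(frame_size, max(xM, xm + 1)); yM <- min(frame_size, max(yM, ym + 1))
      out[[length(out) + 1L]] <- boxes_df(
        frame = gt$frame[i], x_min = xm, y_min = ym, x_max = xM, y_max = yM,
        label = gt$label[i],
        confidence = stats::runif(1L, config$conf_range[1L], config$conf_range[2L]),
        provenance = "detector")
    }
  }

  if (config$false_positive_rate > 0) {
    n_fp <- stats::rpois(n_frames, config$false_positive_rate)
    for (f in which(n_fp > 0L)) {
      for (k in seq_len(n_fp[f])) {
        w <- stats::runif(1L, 0.05, 0.25) * frame_size
        h <- stats::runif(1L, 0.05, 0.25) * frame_size
        xm <- stats::runif(1L, 0, frame_size - w)
        ym <- stats::runif(1L, 0, frame_size - h)
        out[[length(out) + 1L]] <- boxes_df(
          frame = f - 1L, x_min = xm, y_min = ym, x_max = xm + w,
          y_max = ym + h, label = "polyp",
          confidence = stats::runif(1L, config$fp_conf_range[1L],
                                    config$fp_conf_range[2L]),
          provenance = "detector")
      }
    }
  }

  if (length(out) == 0L) return(empty_boxes())
  res <- do.call(rbind, out)
  res <- res[order(res$frame), , drop = FALSE]
  rownames(res) <- NULL
  res
}
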