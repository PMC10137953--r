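# Video adjacent-frame association (VAFA). A detector that flickers leaves
# isolated undetected frames inside otherwise solid polyp sequences; VAFA
# fills them. Once `run_length` (default 5) consecutive frames each hold a
# polyp box at or above the confidence threshold, the boxes of the last
# positive frame are copied into the following frames, one at a time, for
# as long as each consecutive frame pair stays similar (fingerprint Hamming
# distance strictly below `hamming_threshold`, default 9). The chain stops
# at the first dissimilar pair or at the next frame the detector itself
# marked positive.
#
# Rules fixed here: a frame counts toward a run when it has >= 1 detector
# box at/above the confidence threshold; propagated frames never extend a
# run (no self-sustaining chains); propagated boxes copy the source frame's
# geometry and confidence and are flagged provenance = "propagated";
# detector boxes are never altered.

#' VAFA configuration
#'
#' @param run_length number of consecutive polyp-positive frames required
#'   before propagation can start (default 5).
#' @param hamming_threshold fingerprint Hamming distance at which two
#'   frames stop being similar; propagation continues strictly below it
#'   (default 9). With threshold 0 no pair is similar and stabilization is
#'   the identity.
#' @param confidence_threshold minimum detection score for a box to count
#'   as a polyp detection (default 0.4).
#' @return list of class `vafa_config`.
#' @export
vafa_config <- function(run_length = 5L, hamming_threshold = 9L,
                        confidence_threshold = 0.4) {
  run_length <- as.integer(run_length)
  hamming_threshold <- as.integer(hamming_threshold)
  stopifnot(run_length >= 1L,
            hamming_threshold >= 0L, hamming_threshold <= 64L,
            confidence_threshold >= 0, confidence_threshold <= 1)
  structure(list(run_length = run_length,
                 hamming_threshold = hamming_threshold,
                 confidence_threshold = confidence_threshold),
            class = "vafa_config")
}

#' Stabilize per-frame detections by adjacent-frame association
#'
#' Propagates detection boxes from sustained runs of polyp-positive frames
#' into subsequent similar frames (see the rules above). Pass either the
#' frames themselves (fingerprints are computed with
#' [phash_fingerprint()]) or precomputed fingerprints.
#'
#' @param detections [boxes_df()] data frame of detector output for the
#'   whole video (0-based `frame` column).
#' @param n_frames total number of frames in the video.
#' @param frames list of frame images, length `n_frames`; ignored when
#'   `fingerprints` is given.
#' @param fingerprints list of [phash_fingerprint()] objects, length
#'   `n_frames`.
#' @param config a [vafa_config()].
#' @return data frame like `detections` with propagated boxes appended
#'   (provenance `"propagated"`), sorted by frame. Detector rows are
#'   preserved unchanged; the output covers the same `n_frames`.
#' @examples
#' det <- boxes_df(frame = 0:4, x_min = 10, y_min = 10, x_max = 50,
#'                 y_max = 50, confidence = 0.9)
#' fps <- replicate(7, phash_fingerprint(matrix(0.5, 32, 32)),
#'                  simplify = FALSE)
#' out <- vafa_stabilize(det, n_frames = 7, fingerprints = fps)
#' table(out$provenance)
#' @export
vafa_stabilize <- function(detections, n_frames, frames = NULL,
                           fingerprints = NULL, config = vafa_config()) {
  detections <- validate_boxes(detections)
  stopifnot(inherits(config, "vafa_config"))
  n_frames <- as.integer(n_frames)
  if (n_frames == 0L) {
    if (nrow(detections) > 0L) {
      stop("detections reference frames but the video is empty", call. = FALSE)
    }
    return(detections)
  }
  if (is.null(fingerprints)) {
    if (is.null(frames)) {
      stop("supply either 'frames' or 'fingerprints'", call. = FALSE)
    }
    if (length(frames) != n_frames) {
      stop("got ", length(frames), " frames for n_frames = ", n_frames,
           call. = FALSE)
    }
    fingerprints <- lapply(frames, phash_fingerprint)
  }
  if (length(fingerprints) != n_frames) {
    stop("got ", length(fingerprints), " fingerprints for n_frames = ",
         n_frames, call. = FALSE)
  }
  if (nrow(detections) > 0L && max(detections$frame) >= n_frames) {
    stop("detections reference frame ", max(detections$frame),
         " beyond n_frames = ", n_frames, call. = FALSE)
  }

  ct <- config$confidence_threshold
  counted <- detections$confidence >= ct & detections$provenance == "detector"
  positive <- tabulate(detections$frame[counted] + 1L, nbins = n_frames) > 0L

  added <- list()
  i <- 1L
  run <- 0L
  while (i <= n_frames) {
    if (positive[i]) {
      run <- run + 1L
      i <- i + 1L
      next
    }
    if (run >= config$run_length) {
      source_frame <- i - 1L  # last positive frame of the run (1-based)
      src <- detections[detections$frame == source_frame - 1L & counted, ,
                        drop = FALSE]
      prev <- source_frame
      while (i <= n_frames && !positive[i] &&
             phash_distance(fingerprints[[prev]], fingerprints[[i]]) <
               config$hamming_threshold) {
        filled <- src
        filled$frame <- i - 1L
        filled$provenance <- "propagated"
        added[[length(added) + 1L]] <- filled
        prev <- i
        i <- i + 1L
      }
      run <- 0L
      # chain ended at a dissimilar negative frame: it stays empty
      if (i <= n_frames && !positive[i]) i <- i + 1L
    } else {
      run <- 0L
      i <- i + 1L
    }
  }

  out <- rbind(detections, do.call(rbind, added))
  out <- out[order(out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stabilize detections directly from frame images
#'
#' Thin wrapper over [vafa_stabilize()] that fingerprints the frames first.
#'
#' @param frames list of frame images.
#' @inheritParams vafa_stabilize
#' @export
stabilize_video <- function(frames, detections, config = vafa_config()) {
  vafa_stabilize(detections, n_frames = length(frames), frames = frames,
                 config = config)
}
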