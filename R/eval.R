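# Frame-level and video-level evaluation protocol.
#
# Frame rules: a frame is TP when every ground-truth polyp is overlapped by
# at least one predicted box AND no predicted box sits entirely in a
# non-polyp area; any stray box makes the frame FP (FP dominates a partial
# hit); an empty frame with no predictions is TN; a polyp frame with no
# overlapping prediction (or only some polyps covered, without strays) is
# FN. "Overlap" means positive intersection area — no IoU cut-off.

#' Classify one frame against its ground truth
#'
#' @param gt_boxes,pred_boxes [boxes_df()] data frames for a single frame
#'   (the `frame` column is ignored). `pred_boxes` should already be
#'   filtered at the working confidence threshold; see [classify_frames()].
#' @return one of `"TP"`, `"FP"`, `"TN"`, `"FN"`.
#' @examples
#' gt <- boxes_df(0L, 100, 100, 200, 200, provenance = "ground_truth")
#' pr <- boxes_df(0L, 120, 120, 210, 210, confidence = 0.9)
#' classify_frame(gt, pr)  # "TP"
#' @export
classify_frame <- function(gt_boxes, pred_boxes) {
  gt <- validate_boxes(gt_boxes)
  pred <- validate_boxes(pred_boxes)
  if (nrow(gt) == 0L) {
    return(if (nrow(pred) == 0L) "TN" else "FP")
  }
  if (nrow(pred) == 0L) return("FN")
  stray <- vapply(seq_len(nrow(pred)), function(i) {
    !overlaps_any(pred$x_min[i], pred$y_min[i], pred$x_max[i], pred$y_max[i], gt)
  }, logical(1L))
  if (any(stray)) return("FP")
  covered <- vapply(seq_len(nrow(gt)), function(i) {
    overlaps_any(gt$x_min[i], gt$y_min[i], gt$x_max[i], gt$y_max[i], pred)
  }, logical(1L))
  if (all(covered)) "TP" else "FN"
}

#' Classify every frame of a video
#'
#' Applies [classify_frame()] per frame after filtering predictions at the
#' confidence threshold (boxes with `confidence >= threshold` are kept;
#' default 0.4).
#'
#' @param gt,pred [boxes_df()] data frames covering the whole video.
#' @param n_frames total number of frames (frames absent from both data
#'   frames are TN).
#' @param confidence detection-score threshold applied to `pred`.
#' @return character vector of length `n_frames` with values in
#'   `TP/FP/TN/FN`.
#' @export
classify_frames <- function(gt, pred, n_frames, confidence = 0.4) {
  gt <- validate_boxes(gt)
  pred <- validate_boxes(pred)
  pred <- pred[pred$confidence >= confidence, , drop = FALSE]
  vapply(seq_len(n_frames) - 1L, function(f) {
    classify_frame(gt[gt$frame == f, , drop = FALSE],
                   pred[pred$frame == f, , drop = FALSE])
  }, character(1L))
}

#' Video-level majority verdict
#'
#' A video is judged from its per-frame outcomes: if the number of correct
#' frames (TP or TN) strictly exceeds half of the total frame count, a
#' polyp video is TP and a polyp-free video is TN; otherwise the polyp
#' video is FN and the polyp-free video is FP.
#'
#' @param outcomes character vector of frame outcomes (`TP/FP/TN/FN`),
#'   non-empty.
#' @param video_has_polyp logical: does the video truly contain a polyp?
#' @return one of `"TP"`, `"FP"`, `"TN"`, `"FN"`.
#' @examples
#' video_verdict(c(rep("TP", 6), rep("FN", 4)), video_has_polyp = TRUE) # "TP"
#' @export
video_verdict <- function(outcomes, video_has_polyp) {
  if (length(outcomes) == 0L) {
    stop("'outcomes' must contain at least one frame", call. = FALSE)
  }
  if (!all(outcomes %in% c("TP", "FP", "TN", "FN"))) {
    stop("outcomes must be TP/FP/TN/FN", call. = FALSE)
  }
  correct <- sum(outcomes %in% c("TP", "TN"))
  majority <- correct > length(outcomes) / 2
  if (isTRUE(video_has_polyp)) {
    if (majority) "TP" else "FN"
  } else {
    if (majority) "TN" else "FP"
  }
}

#' Tally outcomes into a confusion-count object
#'
#' @param outcomes character vector of `TP/FP/TN/FN` outcomes (frame- or
#'   video-level).
#' @return a `confusion_counts` object (named integer vector).
#' @export
confusion_counts <- function(outcomes) {
  if (!all(outcomes %in% c("TP", "FP", "TN", "FN"))) {
    stop("outcomes must be TP/FP/TN/FN", call. = FALSE)
  }
  counts <- vapply(c("TP", "FP", "TN", "FN"),
                   function(k) sum(outcomes == k), integer(1L))
  structure(counts, class = "confusion_counts")
}

#' Five evaluation metrics from confusion counts
#'
#' Computes, as percentages:
#' \itemize{
#'   \item sensitivity = TP / (TP + FN)
#'   \item specificity = TN / (TN + FP)
#'   \item accuracy = (TP + TN) / (TP + TN + FP + FN)
#'   \item precision = TP / (TP + FP)
#'   \item F1 = 2 * sensitivity * specificity / (sensitivity + specificity)
#' }
#' Note the F1 here is the harmonic mean of sensitivity and *specificity*,
#' not of precision and recall. A metric whose denominator is zero is
#' reported as `NA` (undefined), never as 0.
#'
#' @param counts a `confusion_counts` object, or a named vector/list with
#'   entries `TP`, `FP`, `TN`, `FN`.
#' @return a `metric_set` object: named numeric vector of the five
#'   percentages.
#' @examples
#' compute_metrics(c(TP = 48, FP = 21, TN = 162, FN = 0))
#' @export
compute_metrics <- function(counts) {
  counts <- unlist(counts)[c("TP", "FP", "TN", "FN")]
  if (anyNA(counts) || any(counts < 0)) {
    stop("'counts' must supply non-negative TP, FP, TN and FN", call. = FALSE)
  }
  tp <- counts[["TP"]]; fp <- counts[["FP"]]
  tn <- counts[["TN"]]; fn <- counts[["FN"]]
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  sens <- ratio(tp, tp + fn)
  spec <- ratio(tn, tn + fp)
  acc <- ratio(tp + tn, tp + tn + fp + fn)
  prec <- ratio(tp, tp + fp)
  f1 <- if (is.na(sens) || is.na(spec) || sens + spec == 0) NA_real_ else
    2 * sens * spec / (sens + spec)
  structure(c(sensitivity = sens, specificity = spec, accuracy = acc,
              precision = prec, f1 = f1),
            counts = counts, class = "metric_set")
}

#' @export
print.metric_set <- function(x, digits = 2L, ...) {
  counts <- attr(x, "counts")
  cat("Detection metrics (%):\n")
  for (nm in names(x)) {
    cat(sprintf("  %-12s %s\n", nm,
                if (is.na(x[[nm]])) "undefined" else
                  formatC(x[[nm]], digits = digits, format = "f")))
  }
  if (!is.null(counts)) {
    cat(sprintf("  counts: TP=%d FP=%d TN=%d FN=%d\n",
                counts[["TP"]], counts[["FP"]], counts[["TN"]], counts[["FN"]]))
  }
  invisible(x)
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d TN=%d FN=%d (n=%d)\n",
              x[["TP"]], x[["FP"]], x[["TN"]], x[["FN"]], sum(x)))
  invisible(x)
}

#' Evaluate detections for one video
#'
#' Convenience wrapper: classifies every frame, tallies counts, computes
#' metrics, and (optionally) the video-level verdict.
#'
#' @inheritParams classify_frames
#' @param video_has_polyp logical; when not `NULL` the video-level verdict
#'   is included.
#' @return list with `outcomes`, `counts`, `metrics`, and `verdict` (or
#'   `NULL`).
#' @export
evaluate_video <- function(gt, pred, n_frames, confidence = 0.4,
                           video_has_polyp = NULL) {
  outcomes <- classify_frames(gt, pred, n_frames, confidence)
  counts <- confusion_counts(outcomes)
  list(outcomes = outcomes,
       counts = counts,
       metrics = compute_metrics(counts),
       verdict = if (is.null(video_has_polyp)) NULL else
         video_verdict(outcomes, video_has_polyp))
}
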