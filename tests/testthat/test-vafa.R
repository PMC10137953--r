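stabilize_flags <- function(flags, dists, config = vafa_config()) {
  vafa_stabilize(flags_to_detections(flags), n_frames = length(flags),
                 fingerprints = fingerprints_with_distances(dists),
                 config = config)
}

frames_with_box <- function(det, n_frames, conf = 0.4) {
  counted <- det$confidence >= conf
  sort(unique(det$frame[counted]))
}

test_that("a run of five propagates into the next similar frame", {
  flags <- c(rep(TRUE, 5), FALSE)
  out <- stabilize_flags(flags, dists = c(0, 0, 0, 0, 3))
  prop <- out[out$provenance == "propagated", ]
  expect_identical(prop$frame, 5L)
  # propagated geometry copies the source frame's box
  src <- out[out$frame == 4L, ]
  expect_identical(prop[, c("x_min", "y_min", "x_max", "y_max", "confidence")],
                   setNames(src[, c("x_min", "y_min", "x_max", "y_max", "confidence")],
                            c("x_min", "y_min", "x_max", "y_max", "confidence")),
                   ignore_attr = TRUE)
})

test_that("a run of four never triggers propagation", {
  flags <- c(rep(TRUE, 4), FALSE)
  out <- stabilize_flags(flags, dists = rep(0, 4))
  expect_identical(out, stabilize_flags(flags, dists = rep(0, 4)))
  expect_false(any(out$provenance == "propagated"))
  expect_identical(nrow(out), 4L)
})

test_that("the chain continues while similar and stops at the first dissimilar pair", {
  flags <- c(rep(TRUE, 5), FALSE, FALSE)
  out1 <- stabilize_flags(flags, dists = c(0, 0, 0, 0, 3, 4))
  expect_identical(out1$frame[out1$provenance == "propagated"], c(5L, 6L))
  out2 <- stabilize_flags(flags, dists = c(0, 0, 0, 0, 3, 12))
  expect_identical(out2$frame[out2$provenance == "propagated"], 5L)
  # distance exactly at the threshold is already dissimilar
  out3 <- stabilize_flags(flags, dists = c(0, 0, 0, 0, 9, 0))
  expect_false(any(out3$provenance == "propagated"))
})

test_that("stabilize is the identity when every frame already has a box", {
  flags <- rep(TRUE, 12)
  det <- flags_to_detections(flags)
  out <- stabilize_flags(flags, dists = rep(0, 11))
  expect_identical(out, det)
})

test_that("hamming_threshold = 0 makes stabilize the identity", {
  set.seed(3)
  for (rep in 1:20) {
    flags <- sample(c(TRUE, FALSE), 10, replace = TRUE)
    det <- flags_to_detections(flags)
    out <- stabilize_flags(flags, dists = sample(0:8, 9, replace = TRUE),
                           config = vafa_config(hamming_threshold = 0))
    expect_identical(out, det[order(det$frame), ], ignore_attr = TRUE)
  }
})

test_that("coverage never shrinks and detector boxes are never altered", {
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(3:15, 1)
    flags <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.7, 0.3))
    dists <- sample(0:15, n - 1, replace = TRUE)
    det <- flags_to_detections(flags)
    out <- stabilize_flags(flags, dists)
    # frame-count conservation: no frame index outside the video
    expect_true(all(out$frame >= 0 & out$frame < n))
    # detector rows preserved byte-identical
    kept <- out[out$provenance == "detector", ]
    expect_identical(kept, det[order(det$frame), ], ignore_attr = TRUE)
    # monotone coverage
    expect_true(all(frames_with_box(det, n) %in% frames_with_box(out, n)))
  }
})

test_that("propagation matches the rule oracle on random flag/distance sequences", {
  set.seed(99)
  for (rep in 1:200) {
    n <- sample(2:14, 1)
    flags <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.65, 0.35))
    dists <- sample(c(0, 3, 8, 9, 15), n - 1, replace = TRUE)
    out <- stabilize_flags(flags, dists)
    got <- rep(FALSE, n)
    got[out$frame[out$provenance == "propagated"] + 1L] <- TRUE
    expect_identical(got, oracle_vafa_filled(flags, dists),
                     label = paste("flags", paste(as.integer(flags), collapse = ""),
                                   "dists", paste(dists, collapse = ",")))
  }
})

test_that("boxes below the confidence threshold do not count toward a run", {
  flags <- rep(TRUE, 6)
  det <- flags_to_detections(flags, confidence = c(0.9, 0.9, 0.2, 0.9, 0.9, 0.9))
  out <- vafa_stabilize(det, n_frames = 7,
                        fingerprints = fingerprints_with_distances(rep(0, 6)))
  # longest counted run before frame 6 is 3 (frames 3..5): no propagation
  expect_false(any(out$provenance == "propagated"))
})

test_that("multiple boxes on the source frame are all propagated", {
  det <- rbind(flags_to_detections(rep(TRUE, 5)),
               boxes_df(frame = 4L, x_min = 60, y_min = 60, x_max = 90,
                        y_max = 90, confidence = 0.8))
  out <- vafa_stabilize(det, n_frames = 6,
                        fingerprints = fingerprints_with_distances(rep(2, 5)))
  prop <- out[out$provenance == "propagated", ]
  expect_identical(nrow(prop), 2L)
  expect_setequal(prop$x_min, c(10, 60))
})

test_that("mismatched inputs and empty videos are handled", {
  det <- flags_to_detections(rep(TRUE, 5))
  expect_error(vafa_stabilize(det, n_frames = 5,
                              fingerprints = fingerprints_with_distances(rep(0, 2))),
               "fingerprints")
  expect_error(vafa_stabilize(det, n_frames = 3,
                              fingerprints = fingerprints_with_distances(rep(0, 2))),
               "beyond")
  empty <- vafa_stabilize(boxes_df(), n_frames = 0, fingerprints = list())
  expect_identical(nrow(empty), 0L)
})

test_that("stabilization raises per-image sensitivity on a flickering detector", {
  vid <- synth_video(synth_scene_config(n_frames = 40, frame_size = 96,
                                        change_magnitude = 0.5, seed = 21))
  det <- simulate_detector(vid$gt, vid$n_frames, vid$frame_size,
                           detector_sim_config(miss_probability = 0,
                                               localization_jitter = 1,
                                               false_positive_rate = 0, seed = 8))
  # drop detections on frames 11..13 and 26..27, after solid runs of >= 5
  miss <- det$frame %in% c(10:12, 25:26)
  flickery <- det[!miss, ]
  before <- compute_metrics(confusion_counts(
    classify_frames(vid$gt, flickery, vid$n_frames)))
  out <- stabilize_video(vid$frames, flickery)
  after <- compute_metrics(confusion_counts(
    classify_frames(vid$gt, out, vid$n_frames)))
  expect_gt(after[["sensitivity"]], before[["sensitivity"]])
})
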