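---
title: "Stabilizing and scoring lesion detections in hysteroscopic video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stabilizing and scoring lesion detections in hysteroscopic video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polypstab)
```

## The problem

Endometrial polyps are benign protrusions of the uterine lining that a
gynecologist inspects for during hysteroscopy. A single-frame object
detector run on the live video stream can assist that inspection, but
its raw output is temporally unstable: the same clearly visible lesion
is detected on most frames and inexplicably missed on isolated ones, so
the on-screen box flickers. `polypstab` implements the post-processing
and evaluation machinery for this setting. It is detector-agnostic: any
model that emits per-frame boxes with confidences can be stabilized and
scored.

## Perceptual hashing and frame similarity

Adjacent frames of an endoscopic video are usually near-duplicates.
The package quantifies this with the classic DCT perceptual hash:

1. convert the frame to luminance (ITU-R BT.601 weights
   0.299 R + 0.587 G + 0.114 B);
2. resize bilinearly to 32 × 32;
3. apply the orthonormal 2-D type-II DCT;
4. keep the top-left 8 × 8 coefficient block — the lowest spatial
   frequencies, DC term included;
5. set bit *i* to 1 iff coefficient *i* strictly exceeds the median of
   the 64 retained coefficients (row-major bit order).

Two frames are compared by the Hamming distance of their 64-bit
fingerprints; distances of 9 or more mean the frames are no longer
considered similar (note the orientation: *smaller* distance = *more*
similar). The strict `>` at the median makes a constant frame hash to
all zeros, and because the DC coefficient participates in the median
split, the hash is *not* invariant to adding a constant to every pixel
— a property the test suite asserts with an explicit witness.

One numerical subtlety is handled deliberately: for structured images
(checkerboards, pure sinusoids) most retained coefficients are
mathematical zeros, and their ordering around the median would otherwise
be decided by floating-point summation noise that differs between
mathematically equivalent DCT implementations. Coefficients are
therefore rounded to 10 decimals before the median split. Genuine
coefficient gaps in natural or noisy images are many orders of magnitude
coarser, so the rounding only collapses exact ties.

```{r phash}
img <- matrix(runif(64 * 64), 64, 64)
fp <- phash_fingerprint(img)
fp
phash_distance(fp, phash_fingerprint(img))
```

## The VAFA stabilization rule

The video adjacent-frame association algorithm fills detection gaps
using frame similarity. With the default `vafa_config()`:

* a frame is *polyp-positive* when it holds at least one detector box
  with confidence ≥ 0.4;
* once 5 or more consecutive frames are positive and the next frame is
  not, the boxes of the last positive frame are copied into it provided
  the two frames' fingerprint distance is < 9;
* the chain continues frame by frame while each consecutive pair stays
  similar, and stops at the first pair with distance ≥ 9 or at the next
  detector-positive frame.

Three rules close gaps the verbal description leaves open, each chosen
to keep the algorithm conservative:

* **Propagation never overrides the detector.** Frames with their own
  qualifying detection keep it unchanged; propagation only fills empty
  frames. The algorithm's purpose is fixing unstable boxes, not
  second-guessing the model.
* **Propagated frames do not extend runs.** Only detector-positive
  frames advance the run counter, so a single 5-frame run cannot
  self-sustain indefinitely through its own propagated boxes; after a
  chain ends, a fresh run of 5 genuine detections is required.
* **Frame-level trigger, box-level copy.** A run is counted on "frame
  contains ≥ 1 polyp box"; when the source frame holds several boxes,
  all are propagated with their confidences (no re-scoring rule exists,
  so confidence is inherited).

Whole-frame similarity is used (the hash operates on images, and no
crop-to-box variant is defined); `run_length`, `hamming_threshold` and
`confidence_threshold` are all configurable.

```{r vafa}
det <- boxes_df(frame = c(0:4, 6), x_min = 20, y_min = 20,
                x_max = 60, y_max = 60, confidence = 0.9)
# a static clip: every pair of frames is similar
frames <- replicate(8, array(0.5, c(64, 64, 3)), simplify = FALSE)
out <- stabilize_video(frames, det)
out[out$provenance == "propagated", c("frame", "x_min", "confidence")]
```

Only frame 5 — the gap right after the 5-frame run — receives a copy of
frame 4's box. The chain then stops at detector-positive frame 6, which
keeps its own detection, and frame 7 stays empty: the run counter
restarts at frame 6 and a single positive frame does not qualify. The
six detector rows are untouched.

## Evaluation protocol

Frame level: a frame is **TP** when every ground-truth polyp is
overlapped by at least one prediction *and* no prediction lies entirely
in a non-polyp area; any stray prediction makes the frame **FP** (the
stray dominates a partial hit); an empty frame with no predictions is
**TN**; a polyp frame with no overlapping prediction — or with only
some of several polyps covered, without strays — is **FN**. "Overlap"
is positive intersection area; no IoU cut-off is applied, which is the
strictest literal reading of "overlapped". Predictions are filtered at
confidence ≥ 0.4 before classification.

Video level: if the number of correct frames (TP or TN) *strictly*
exceeds half the frame count, a polyp video is TP and a polyp-free
video is TN; otherwise FN / FP respectively.

Five metrics are reported as percentages, with zero-denominator cases
returned as explicit `NA` rather than 0. The F1 here is the harmonic
mean of sensitivity and **specificity** — a deliberate departure from
the precision/recall F1, kept because it is the definition the
evaluation protocol prescribes:

```{r metrics}
compute_metrics(c(TP = 48, FP = 21, TN = 162, FN = 0))
```

## Group normalization and the loss composition

`group_normalize()` standardizes a 4-D `(N, C, H, W)` activation tensor
within channel groups of each sample (population variance, stabilizer
`eps = 1e-5`, optional per-channel affine `gamma`/`beta`). The group
count defaults to `G = 32`; `G = 1` reproduces layer normalization and
`G = C` instance normalization, both verified in the tests against
direct implementations. Because statistics never cross the batch axis,
each sample's output is independent of batch composition — the property
that makes the operator attractive for memory-bound video training where
batches are small.

`total_loss()` composes the three detector-head loss sums:
`L = reg_weight · L_reg / N_pos + L_cls / N_pos + L_obj / N_pos`, with
`reg_weight = 5.0` by default and `N_pos ≥ 1` required (a batch without
positive labels has no defined loss and is rejected). The component
losses themselves are inputs: their internal form belongs to the
detector, not to this toolkit.

## Mosaic and mixup augmentation

`augment_mosaic()` letterboxes four annotated images to the output size
(aspect-preserving scale `min(s/W, s/H)`, top-left anchored, mid-gray
114/255 pad — a fixed documented pad color that avoids biasing
intensity statistics), lays them out around a center point sampled
uniformly from the middle half of the canvas (guaranteeing four
non-degenerate tiles), and remaps every box by its tile's
scale-then-translate transform, clipping to the tile's quadrant and
dropping boxes that lose all area. `augment_mixup()` applies mild,
seeded photometric jitter (±10% brightness/contrast), translation
(±5% of each axis) and a probability-0.5 horizontal flip to the second
image, then blends the pair 1:1 and unions the (transformed) box sets.
No additional per-tile random rescale is applied in mosaic — pure
aspect-preserving fit, the minimal reading of the procedure.

## The synthetic data generator

Because no clinical recordings ship with the package, every end-to-end
path is exercised on generated scenes built from the features the
algorithms actually consume:

* a **smooth reddish background** (coarse uniform noise bilinearly
  upsampled; one blob ≈ 16 px) whose crop window drifts 1.5 px/frame at
  `change_magnitude = 1` — this drift is what gives consecutive frames
  small but nonzero Hamming distances;
* an optional **bright soft-edged ellipse** (radii 18 × 12 px by
  default on a 128 px frame, logistic edge profile) drifting ~0.6
  px/frame, with the axis-aligned bounding box of the ellipse as
  per-frame ground truth;
* `change_magnitude` scales *all* temporal variation, so 0 yields a
  perfectly static clip (useful for exact-identity tests) and larger
  values let tests drive frames apart deliberately.

The **flickering detector** simulator emits each ground-truth box with
probability `1 − miss_probability` (default 0.2 — a detector that is
usable but visibly unstable), jitters each box edge by up to 2 px,
draws true-box confidences from U(0.45, 0.95), and adds spurious boxes
at a Poisson rate of 0.05/frame with confidences from U(0.05, 0.9) —
deliberately straddling the 0.4 working threshold so that confidence
filtering is exercised. All randomness flows from explicit seeds;
identical configurations reproduce byte-identical fixtures.

What passing tests on these scenes **does** show: the propagation rule,
similarity thresholding, box bookkeeping, evaluation arithmetic and
their interaction behave exactly as specified, including the key
end-to-end property that stabilization can only add boxes to frames
following genuine detection runs — raising sensitivity on flickery
positive clips while provably leaving polyp-free clips untouched unless
the detector itself hallucinates a 5-frame run. What it does **not**
show: performance on real tissue, where occlusion by floating
endometrium, specular highlights and camera shake produce failure modes
the renderer does not model.

## Problem sizes and numerical choices

* Acceptance-level checks run the propagation rule exhaustively over
  every polyp-flag sequence of length ≤ 8 under several
  distance patterns (2,040 cases against an independently coded rule
  oracle), compare the hash bit-for-bit with a brute-force double-sum
  DCT oracle on 100 random images, and verify the end-to-end
  sensitivity/specificity property on ten 100-frame synthetic videos —
  sizes at which each property is checked exactly, in seconds.
* Ties in the DCT median split go to bit 0 (strict `>`); coefficients
  are rounded to 10 decimals first (see above).
* Group normalization uses the biased variance estimator, the standard
  choice for normalization layers, fixed so oracles match exactly.
* Box coordinates are 0-based half-open `[x_min, x_max)`; COCO
  `[x, y, w, h]` and VOC 1-based inclusive corners are converted at the
  I/O boundary. "Overlap" therefore means strictly positive
  intersection area — boxes that merely share an edge do not overlap.
* Frame files are ordered by natural sort (`frame_2` < `frame_10`);
  lexicographic ordering would silently shuffle adjacent frames and
  corrupt the association algorithm.

## Known limitations

* Whole-frame hashing means a large lesion moving against a static
  background can keep frames "similar" long after the lesion has moved;
  the propagated box geometry is frozen, not tracked. Learned trackers
  are out of scope by design.
* The evaluation protocol scores frames, not lesion identities: with
  several polyps per frame, per-lesion credit assignment is not
  attempted beyond the all-covered / stray-box rules.
* The mosaic center is sampled from the middle half of the canvas; more
  aggressive crops (centers near the border) are expressible via the
  explicit `center` argument but are not the default.
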