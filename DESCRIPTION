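Package: polypstab
Title: Temporal Stabilization and Evaluation of Lesion Detections in
    Hysteroscopic Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detector-agnostic post-processing and evaluation toolkit for
    endometrial-polyp detection in hysteroscopic video. Implements a 64-bit
    DCT perceptual hash with Hamming-distance similarity, the video
    adjacent-frame association (VAFA) rule that propagates detection boxes
    from sustained polyp-positive runs into similar subsequent frames, group
    normalization over (N, C, H, W) feature tensors, the composite detection
    loss, mosaic and mixup bounding-box augmentation, and a frame-level /
    video-level evaluation protocol reporting sensitivity, specificity,
    accuracy, precision and the sensitivity-specificity F1. A synthetic
    hysteroscopy video generator with a simulated flickering detector makes
    the whole pipeline testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
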