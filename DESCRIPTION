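Package: sdwave
Title: Noninvasive Detection and Tracking of Spreading Depolarizations in Scalp EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects and tracks spreading depolarizations (SDs) in low-density
    (10-20 montage) scalp EEG of decompressive-hemicraniectomy patients. EEG is
    band-pass filtered and masked for poor-quality segments, per-channel power
    depressions are extracted from RMS power envelopes with a first-derivative
    kernel, projected onto a cylindrical scalp map, thresholded into binary
    wavefront images, and tracked with dense optical flow mapped onto a
    spherical head model. Oriented bounding boxes are scored by an effective
    propagation measure, propagation-speed constraints, and spatiotemporal
    consistency, and stitched into a binary detection trace. Includes the
    windowed TPR/FPR/PPV evaluation framework with quality gating and weighted
    bootstrap intervals, leave-2-out cross-validation with ROC threshold
    averaging, a square-root regression estimating SD frequency in 30-hour
    windows, and a synthetic SD-EEG simulator for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
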