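Package: pupilloc
Title: Coarse-to-Fine Pupil Localisation by Adaptive-Kernel Template Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Locates the pupil centre within low-resolution eye images using a
    two-pass (horizontal, then vertical) normalised-correlation template match
    with an adaptively resized iris kernel, white-rim padding so rim positions
    remain matchable at extreme gaze, and a dynamic 90th-percentile threshold
    for candidate selection. Includes eye-frame extraction from facial
    landmarks with a frame-validity gate, standard eye-centre evaluation
    metrics (worst/best eye centre error, a frame-standardised Euclidean
    distance, per-axis absolute error and R-squared, accuracy-versus-threshold
    curves), a synthetic eye-image generator with exact ground truth for
    end-to-end testing, annotation/detection file readers and writers, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
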