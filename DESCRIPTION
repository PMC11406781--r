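Package: MLGait
Title: Single-Camera Two-Dimensional Markerless Sagittal Gait Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Video-based two-dimensional markerless gait analysis for the
    sagittal plane, aimed at quantifying gait in ambulatory children with
    cerebral palsy. Implements color-filter segmentation of sock-colored
    foot segments and pen-marked bony landmarks against a green background,
    landmark tracking, hip/knee/ankle joint kinematics and foot orientation,
    zero-velocity gait-event detection (initial contact and toe-off),
    spatio-temporal parameters (gait speed, step length), and rule-based
    classification of sagittal gait patterns (true equinus, jump, apparent
    equinus, crouch) with deviation flags for mild patterns. A parametric
    sagittal-plane walker simulator and scene renderer provide ground-truthed
    landmark trajectories and RGB frames so the whole pipeline can be
    validated without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    signal,
    jsonlite,
    yaml,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
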