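Package: gazetrack
Title: Head-Motion-Robust Webcam Gaze-Point Estimation and Eye-Movement Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates on-screen gaze points from facial-landmark streams captured
    by a single ordinary webcam, tolerating natural head movements. Implements a
    five-point calibration that maps pupil-center displacement to screen
    coordinates through per-eye scale coefficients, perspective-n-point head-pose
    recovery with checkerboard camera calibration, head-state detection with
    head-pointing geometry, and dynamic updating of the reference-point and
    pupil-center benchmarks after head motion. Ships downstream eye-movement
    analytics (velocity-threshold fixation/saccade classification, gaze heatmaps,
    visual-angle accuracy reports) and a synthetic rigid-head/eyeball rig that
    renders landmark streams with ground truth, so the whole pipeline can be
    validated end to end without a camera or human subjects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    minpack.lm,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
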