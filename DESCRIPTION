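Package: ghtrack
Title: Keypoint-Based Generalized Hough Transform Tracking for Surgical Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tracking-by-detection of a rigid textured target (typically a
    surgical instrument head) in endoscopic video. Each frame is searched
    globally with a Generalized Hough Transform over scale-space keypoints:
    matched keypoints cast rotation-invariant annulus votes for the object
    center, vote weights come from a recursive Bayesian foreground/background
    colour-histogram segmentation model, and in-plane rotation and scale are
    estimated from the positive (center-supporting) keypoints after voting.
    An explicit model-adaptation and reset state machine recovers the target
    after occlusion and out-of-view excursions, and the recovered 2D pose
    (u, v, theta, s) can be lifted to an initialisation of a 3D pose via a
    pinhole camera model. Includes a ground-truthed synthetic sequence
    generator for the standard occlusion/out-of-view/long-term challenge
    regimes, and tracker evaluation tools (center location error, precision
    curves, AUC, box statistics).
License: MIT
Encoding: UTF-8
Imports:
    stats,
    grDevices,
    utils,
    tibble,
    dplyr,
    ggplot2,
    jsonlite,
    generics,
    png
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
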