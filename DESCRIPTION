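Package: poseflow
Title: Temporal Optical-Flow Aggregation for Markerless Pose Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for multi-frame markerless animal pose estimation:
    conversion of keypoint annotations to truncated-Gaussian heatmap labels,
    adjusted percentage-of-correct-keypoints (aPCK) and RMSE evaluation,
    dense Farneback optical flow with per-keypoint temporal aggregation of
    heatmap predictions across a frame window, and two-view coordinate
    correction for camera pairs sharing an axis. Includes a seeded synthetic
    articulated-scene simulator with occlusion episodes and a paired
    orthogonal view for end-to-end validation, plus dataset splitting and
    keypoint-consistent augmentation (rotation, flips, area-relation
    resizing).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    png,
    tiff,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
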