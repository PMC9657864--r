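Package: fallsafe
Title: Fall Prediction from Skeleton Key-Point Kinematics with LSTM Classifiers
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <maintainer@example.org>
Description: Predicts human falls from video-derived skeleton key points
    (nose, left shoulder, left hip). Computes per-frame kinematic features
    (key-point angles to the image origin, angular rates, nose-to-hip height
    ratio), segments feature streams into fixed-length non-overlapping
    windows, and trains two-layer LSTM binary classifiers (the 4p/5p/6p-SAFE
    variants, distinguished only by their input feature sets) to separate
    falls from activities of daily living. Includes a two-rod synthetic
    skeleton-motion simulator producing labelled key-point streams with
    fall and ADL dynamics, so the full pipeline is reproducible without
    video data, plus confusion-matrix evaluation and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'evaluation.R'
    'fallsafe-package.R'
    'features.R'
    'keypoints-io.R'
    'lstm-engine.R'
    'model.R'
    'pipeline.R'
    'simulate.R'
    'utils.R'
    'windows.R'
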