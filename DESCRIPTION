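Package: gazedx
Title: Gaze-Based Classification of Neurodevelopmental Disorders from
    Facial-Emotion-Identification Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for 120 Hz eye-tracking data recorded while
    participants identify facial emotions. Implements velocity-threshold
    (I-VT) fixation and saccade detection, area-of-interest fixation-sample
    counts and scan-path length, trial validity filtering, gaze-retention
    heat-map imaging, per-trial classification with a small multilayer
    perceptron or convolutional network, participant-level aggregation by
    hard voting or a per-stimulus random-forest weighting, nested
    leave-one-participant-out evaluation with exact binomial tests against
    chance, and Welch/Benjamini-Hochberg group statistics. Includes a
    synthetic gaze-cohort generator so the full pipeline is testable
    without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    randomForest,
    yaml,
    data.table,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2,
    optparse
Config/testthat/edition: 3
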