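Package: eegvet
Title: EEG-Based Virtual Eye Tracking via SOBI and Ocular Component Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tracks gaze position from multichannel EEG alone. Decomposes
    continuous EEG with second-order blind identification (SOBI, joint
    approximate diagonalization of time-lagged covariance matrices),
    automatically identifies the horizontal and vertical ocular components
    by combining saccade-related-potential discriminant indices with
    scalp-topography similarity indices (DANS), fits an individual-specific
    linear model mapping component amplitudes to on-screen gaze coordinates,
    and evaluates tracking with visual-angle accuracy, RMS precision, and
    smooth-pursuit trajectory RMSE. Includes a forward-model simulator that
    generates dot-tracking calibration and smooth-pursuit test sessions with
    ground-truth gaze, so the whole pipeline is verifiable without human
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
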