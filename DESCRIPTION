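Package: solestep
Title: Multi-Activity Step Counting from a Sole-Embedded IMU via Foot-Flat
    Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Detects foot-flat (stance) phases in 200 Hz six-axis inertial
    recordings from an IMU embedded under the heel of a shoe, using a windowed
    many-to-one LSTM classifier trained on video-annotated foot-status labels,
    and converts the detected foot-flat stream into step counts with a
    refractory-period ("rest delay") rule. Includes a synthetic multi-activity
    gait simulator (walking at several speeds, running, stomping, high knees,
    butt kicks, stair descent) with ground-truth step events for end-to-end
    validation, channel selection by Pearson correlation with foot status,
    subject-wise k-fold cross-validation, rest-delay sweeps, and a two-stage
    (random then local) hyperparameter search over the model design space.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
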