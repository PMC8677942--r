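Package: ERGdx
Title: Photopic ERG Waveform Features, PhNR Statistics, and Time-Series
    Classification of Optic Neuropathy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing averaged photopic full-field
    electroretinogram (ERG) waveforms recorded with portable skin-electrode
    devices, aimed at detecting optic neuropathy from the photopic negative
    response (PhNR). Provides an S4 container for waveform cohorts, linear
    detrending and extraction of user-defined features (baseline, a-wave,
    b-wave, fixed-latency and trough-averaged PhNR, P- and W-ratios) with
    automated quality control, linear generalized estimating equations with
    robust standard errors for eye-level group comparisons clustered by
    subject, ROC and Youden-index diagnostic evaluation with both standard
    and literal-definition metric variants, a subject-grouped stratified
    benchmark of time-series classifiers (nearest-neighbour dynamic time
    warping, time-series forest, support vector machines, random forest,
    gradient boosting, and a compact LSTM), and a calibrated synthetic
    cohort generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml,
    e1071,
    randomForest,
    xgboost,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
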