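Package: exhalr
Title: Time-Frequency Analysis of Forced-Exhalation Audio for Lung-Age
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for digital-spirometry research on forced-exhalation
    recordings: WAV input, resampling and validation; a synthetic
    blow-sound generator with flow-shaped envelopes; spirometer-like
    decibel features from short-time Fourier spectrograms; Choi-Williams
    time-frequency distributions with 38 derived band, entropy and moment
    features; a correlation/PCA/SMOTE feature-prescreening chain; and
    evaluation of age-group classifiers with cross-validation and paired
    significance tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    class,
    e1071,
    jsonlite,
    MASS,
    nnet,
    randomForest,
    Rcpp,
    rpart,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
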