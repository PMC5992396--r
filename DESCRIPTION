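Package: brakesense
Title: Detection of Emergency-Braking Intention from Driver EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting emergency-braking intention
    from electroencephalography (EEG) recorded during simulated driving. The
    package ships a seeded generator of synthetic driving sessions (multi-rate
    vehicular, EEG and EMG channels with planted slow pre-movement potentials,
    visual evoked components and leg-muscle bursts), signal preprocessing
    (rate harmonization, zero-phase Chebyshev filtering, common average
    referencing, stimulus/response detection, segmentation and automated
    segment rejection), event-related epoching into time-domain feature maps,
    two classifiers (a small convolutional neural network trained by
    stochastic gradient descent, and a soft-margin support vector machine),
    evaluation protocols anchored to an exact-binomial significant chance
    level (repeated stratified holdout, ROC/AUC, rank-based tests,
    per-participant, pooled and leave-one-participant-out designs), and
    behavioral analyses of braking reaction times and the Hilbert-envelope
    leg-movement signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    e1071,
    graphics,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
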