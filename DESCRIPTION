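Package: sleepwave
Title: Optimal Biorthogonal Wavelet Filter Banks for Six-Stage Sleep EEG Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated six-class sleep-stage scoring (W, S1-S4, REM) from EEG
    epochs of 30 s. Designs linear-phase optimal biorthogonal wavelet filter
    banks whose analysis lowpass is a halfband filter, via equality-constrained
    convex quadratic (eigenfilter-style) minimization of stopband energy and
    time-frequency concentration under regularity and perfect-reconstruction
    constraints. Epochs are decomposed into six sub-bands by a five-level
    wavelet transform; l1, l2 and l-infinity norms of the sub-band coefficients
    form the feature set fed to an ensemble of bagged CART trees, evaluated by
    repeated stratified 10-fold cross-validation with confusion matrices,
    Cohen's kappa, per-class one-vs-rest accuracy, F1 and one-vs-rest ROC.
    Includes a stage-conditioned synthetic EEG generator, EDF and plain-text
    hypnogram readers and writers, class rebalancing by random over- and
    under-sampling, and one-way ANOVA with Fisher LSD feature screening.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    randomForest,
    rpart,
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
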