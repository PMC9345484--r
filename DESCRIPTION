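Package: oculocardiac
Title: Linking Oculomotor Metrics to Heart Rate in Naturalistic Viewing
Version: 0.1.0
Authors@R:
    person("Jan", "Vermeulen", email = "jan.vermeulen@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline relating oculomotor behaviour to cardiac
    activity during long naturalistic viewing sessions. Classifies 1 kHz gaze
    traces into fixations, saccades and blinks (Savitzky-Golay smoothing,
    adaptive velocity threshold, amplitude/duration merging criteria),
    estimates beats-per-minute heart rate from 100 Hz pulse-oximetry segments,
    cuts sessions into 30 s chunks with per-participant z-score binarization of
    heart rate, builds three per-chunk feature aggregation schemes (averaging,
    statistical-descriptor explosion, explosion plus PCA reduction), and
    evaluates regression and classification models (logistic regression,
    k-nearest neighbours, random forest) with repeated stratified splits,
    random hyperparameter search, permutation importance and importance
    t-tests. Includes a generator of synthetic arousal-coupled gaze and
    pulse recordings with ground truth so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    data.table,
    FNN,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
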