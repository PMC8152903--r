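Package: erpdecode
Title: Multivariate ERP Decoding of Face Identity and Expression Across
    Perception and Working Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of a multivariate event-related
    potential (ERP) decoding pipeline for face identity and facial
    expression during perception and working memory maintenance.
    Provides an epoched-EEG container with file round-tripping, a
    synthetic epoch generator with known ground truth (class-specific
    scalp topographies, dissociable temporal envelopes, autocorrelated
    noise, previous-trial reactivation), signal conditioning (zero-phase
    FIR low-pass, baseline correction, moving-average smoothing, window
    averaging), an error-correcting output-codes (ECOC) one-vs-rest
    linear-SVM decoder with averaged 3-fold cross-validation and
    iterated random subsampling, temporal generalization and
    cross-dimension decoding, cluster-based permutation inference with
    test-label relabeling and condition-swap nulls, and the JZS
    one-sample Bayes factor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    signal,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071
Config/testthat/edition: 3
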