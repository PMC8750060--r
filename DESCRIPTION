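Package: fccnn
Title: Frequency Channel-Based CNN for EEG Depression Classification and Its Entropy Interpretation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a lightweight frequency channel-based convolutional
    neural network (FCCNN) for binary classification of multichannel EEG
    segments (major depressive disorder versus healthy controls), together
    with a model-interpretation pipeline: activation maximization of the
    input layer, affinity-propagation clustering of the resulting activation
    values, Shannon entropy over the adaptive clustering partitions, and
    projection of per-channel entropies onto 10-20 scalp topographies and
    brain regions. A synthetic-EEG cohort generator with class-discriminative
    spectral peaks makes the full pipeline testable without access to
    clinical recordings. Includes EDF and plain-text cohort I/O, subject-level
    train/test splitting, stratified cross-validation, ROC/AUC, and pairwise
    Welch t-test comparison matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    data.table,
    pROC,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
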