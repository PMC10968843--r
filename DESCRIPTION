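Package: ivens
Title: Interval-Valued Heterogeneous Ensemble Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ensemble classification for high-dimensional multi-class data
    (e.g. microarray gene expression) based on interval modeling. Groups of
    heterogeneous base classifiers (random forests, multilayer perceptrons,
    support vector machines, k-nearest neighbours) produce per-class soft
    labels; each group is summarised by a per-class interval spanning its
    members' scores, intervals are combined with one of ten interval-valued
    aggregation functions, and the decision is taken under an admissible
    linear order on intervals (Xu-Yager or lexicographical). Two entropy
    variants prune weak member models and whole groups by mean cross-entropy
    loss estimated with repeated stratified two-fold cross-validation. A
    seeded generator of microarray-like data and an evaluation harness
    (stratified repeated splits, min-max scaling, one-vs-one ROC AUC,
    accuracy, balanced accuracy) are included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    e1071,
    graphics,
    jsonlite,
    ranger,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp,
    RcppArmadillo
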