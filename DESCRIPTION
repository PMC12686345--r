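Package: cafspec
Title: Label-Free Raman Classification of Pancreatic Fibroblast Subtypes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-cell Raman microspectroscopy chemometrics:
    simulation of hyperspectral cell maps with hierarchical (cell- and
    pixel-level) variability, spectral preprocessing (iterative modified
    polynomial baseline removal, Savitzky-Golay smoothing, internal-standard
    normalization at the paraformaldehyde 1040 1/cm band), partial least
    squares discriminant analysis fitted by NIPALS with variable importance
    in projection (VIP) band selection, and full classification evaluation
    (stratified or cell-grouped splits, confusion matrices, one-vs-rest
    ROC/AUC, k-fold cross-validation, per-band two-sample t statistics).
    Designed around the three-class problem of distinguishing human
    pancreatic stellate cells (HPaSC) from induced inflammatory (iCAF) and
    myofibroblastic (myCAF) cancer-associated fibroblasts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    Matrix,
    Rcpp,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    mixOmics,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp,
    RcppArmadillo
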