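Package: flexstates
Title: Static and Dynamic Resting-State Features for Case-Control
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts static (fALFF in the slow-5 and slow-4 bands,
    regional homogeneity, binary and weighted degree centrality) and
    dynamic (multilayer-network node flexibility over a resolution by
    coupling parameter grid, Gaussian hidden-Markov-model fractional
    occupancies and switching rate) features from resting-state fMRI
    parcel time series or 4D volumes, runs three feature-selection
    schemes (Spearman top fraction, LASSO, t-test plus LASSO) inside
    stratified cross-validation, and evaluates four-kernel support
    vector machine classifiers with ROC/AUC metrics and label-permutation
    testing. Includes a synthetic two-group cohort generator with
    planted state dynamics and regional deficits so the full pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    Rcpp,
    glmnet,
    e1071,
    jsonlite,
    RNifti
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
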