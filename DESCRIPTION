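Package: sparseMIL
Title: Sparse-Representation Multi-Instance Learning for Breast
    Ultrasound Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A multi-instance learning (MIL) pipeline for classifying
    breast-ultrasound-style region-of-interest (ROI) images as benign or
    malignant. Provides ROI enhancement operators (neighbour-tissue
    suppression, least-squares background correction, gamma transform,
    Gaussian smoothing), concentric-circle bag-of-visual-words feature
    extraction with latent Dirichlet allocation topic reduction, K-SVD
    dictionary learning with an l1 coordinate-descent sparse coder to embed
    instance bags as fixed-length feature vectors, a sparse-Bayesian
    relevance vector machine classifier combined into an ensemble over
    dictionary sizes, and a stratified cross-validation evaluation protocol
    with sensitivity, specificity, accuracy and ROC/AUC reporting. Includes
    generators for synthetic ultrasound phantoms and feature-space bags so
    the whole pipeline is testable without external data, and a loader for
    the Breast Cancer Wisconsin (Original) tabular dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    png,
    tiff,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    glmnet,
    EBImage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
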