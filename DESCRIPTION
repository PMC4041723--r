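Package: fundusBoVW
Title: Bag-of-Visual-Words Lesion Detection for Retinal Fundus Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A bag-of-visual-words (BoVW) framework for detecting diabetic-retinopathy
    lesions (hard exudates, hemorrhages, red lesions, cotton-wool spots, drusen) in
    colour fundus photographs. Provides field-of-view masking, sparse interest-point
    detection with a determinant-of-Hessian backend and upright SURF-style 128-d
    descriptors, dense multi-scale grid sampling, class-aware visual codebooks learned
    by per-class k-means, hard, soft (codeword uncertainty) and semi-soft descriptor
    coding with sum or max pooling, per-lesion RBF-SVM detectors with cross-validated
    grid search, a meta-classification referral decision evaluated under 5x2-fold
    cross-validation, ROC/AUC evaluation with a standardized-AUC treatment comparison,
    and a seeded synthetic fundus generator emulating a cross-dataset protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    e1071,
    jsonlite,
    withr,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
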