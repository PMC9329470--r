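Package: silfat
Title: Body Fat Distribution Estimation from Binary Body Silhouettes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates visceral (VAT), abdominal subcutaneous (ASAT) and
    gluteofemoral (GFAT) adipose tissue volumes and the VAT/ASAT ratio from
    binary coronal and sagittal body silhouettes. Provides a synthetic
    body-phantom population generator with labelled adipose compartments,
    a silhouette construction pipeline (axial segmentation, orthogonal
    projection, aspect correction, panel composition), a multi-task
    convolutional regressor trained under nested cross-validation with
    mean-ensembling, sex-stratified linear anthropometric benchmark models
    with bootstrap confidence intervals, and downstream cardiometabolic
    disease association analyses (logistic and Cox models per standard
    deviation of exposure, quintile gradients, and standardized prevalence
    within body-mass-index and waist-circumference strata).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    grDevices,
    Rcpp,
    RNifti,
    png,
    jsonlite,
    yaml,
    withr,
    survival,
    EBImage
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
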