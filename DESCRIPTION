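Package: radvox
Title: 3D Radiomics Extraction and Nested Cross-Validated Classification
    for Paired-Sequence MRI Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Masked 3D radiomic feature extraction and small-cohort
    classification for paired-sequence MRI (post-gadolinium T1 and T2),
    built for the problem of separating skull base chordoma from
    chondrosarcoma. Provides an undecimated single-level Coiflet-1 wavelet
    decomposition, fixed-bin-number intensity discretization, morphology,
    intensity and histogram features, five gray-level texture-matrix
    families (GLCM, GLRLM, GLSZM, NGLDM, NGTDM) computed in 3D over a
    volume of interest, canonical feature naming and z-score
    normalization, logistic-regression recursive feature elimination with
    frequency voting and correlation pruning, grid-searched logistic
    regression and support vector machine models with nested
    cross-validation, repeated k-fold ROC/AUC evaluation, hold-out
    testing, and a seeded synthetic two-class phantom generator for
    end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    e1071,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
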