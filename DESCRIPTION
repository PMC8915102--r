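Package: pcarad
Title: Radiomics Pipeline for Prostate Cancer Diagnosis from Multiparametric MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computer-aided diagnosis pipeline for prostate cancer from
    diffusion-weighted and T2-weighted MR volumes. Computes voxel-wise apparent
    diffusion coefficient (ADC) maps at multiple b-values and summarises them as
    cumulative-distribution functional features; extracts 3D first-order, gray-level
    co-occurrence (26-neighbour GLCM) and run-length (GLRLM) texture features from
    the whole prostate; describes lesion shape by spherical-harmonics reconstruction
    errors after an attraction-repulsion spherical parameterization of the lesion
    surface mesh; fuses the features with the PSA biomarker; reduces them by
    bi-directional stepwise logistic selection; and evaluates SVM, random forest,
    decision tree and LDA classifiers under k-fold and leave-one-out
    cross-validation. Includes a synthetic phantom generator with class-conditional
    diffusion, texture, shape and PSA structure for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    e1071,
    randomForest,
    rpart,
    MASS,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
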