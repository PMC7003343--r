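Package: waveRadiomics
Title: Wavelet-Transformed 3D Radiomics for Predicting Treatment Response
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end 3D radiomic analysis of contrast-enhanced MRI lesion
    volumes for predicting pathological complete response to neoadjuvant
    chemotherapy. Computes 88 volumetric texture features (shape, histogram,
    gray-level co-occurrence, run-length and zone-size matrices), 77 features
    in a 10 mm peritumoral band, and 616 features on the eight subbands of a
    single-stage stationary 3D wavelet decomposition; performs Boruta-style
    all-relevant feature screening followed by iterative leave-one-feature-out
    AUC culling; balances classes with SMOTE and evaluates six random-forest
    feature-group models by repeated stratified 10-fold cross-validation.
    Includes a synthetic-cohort generator with class-dependent lesion size and
    intratumoral texture grain so the full pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    randomForest,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
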