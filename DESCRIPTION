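Package: radicc
Title: Robustness of CT Angiography Texture Radiomics Under Segmentation
    Perturbation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to assess the robustness of higher-order texture radiomics
    extracted from contrast-enhanced carotid CT angiography. The package
    generates synthetic paired culprit/non-culprit artery phantoms with
    controllable wall texture, applies systematic region-of-interest
    perturbation by binary dilation and erosion, extracts 93 unfiltered
    radiomic features (first-order, GLCM, GLRLM, GLSZM, GLDM, NGTDM) under a
    grid of pre-processing and grey-level quantisation settings, categorises
    feature robustness by two-way mixed-effects intraclass correlation, prunes
    redundant features by Spearman correlation, and compares cross-validated
    culprit-artery classifiers with DeLong and Wilcoxon signed-rank tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    RNifti,
    oro.nifti,
    glmnet,
    randomForest,
    rpart,
    nnet,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
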