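Package: soylodge
Title: Soybean Lodging Classification from UAV Imagery Texture Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for classifying lodging severity of
    soybean breeding plots from aerial (UAV) imagery. Provides a synthetic
    plot-field generator, Chan-Vese active-contour canopy segmentation,
    gray-level co-occurrence matrix (GLCM) texture features (the 14 Haralick
    statistics), random-forest recursive feature elimination, five SMOTE-family
    treatments for class imbalance (SMOTE-Tomek, SMOTE-ENN, Borderline-SMOTE,
    SMOTE-NC, ADASYN), four classifiers (XGBoost, random forest, k-nearest
    neighbours, single-hidden-layer neural network) behind one contract, and a
    full evaluation suite (confusion matrix, precision/recall/F1, overall
    accuracy, Cohen's kappa, one-vs-rest ROC/PR curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    nnet,
    png,
    randomForest,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    xgboost,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
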