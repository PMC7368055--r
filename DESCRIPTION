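Package: thrombospot
Title: Multiparameter Phenotyping of Platelet-Fibrin Thrombus Formation Under Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for microspot-based whole-blood flow assays of thrombus
    formation. Quantifies multicolour time-lapse microscopy (background
    suppression, baseline-referenced thresholding, morphological cleanup,
    percent surface-area coverage), derives the nine-parameter kinetic
    signature of platelet adhesion, thrombus structure and fibrin formation
    (including the time-to-fibrin statistic), characterizes thrombin-generation
    curves (lag time, endogenous thrombin potential, peak), and provides the
    comparative analytics layer: 0-10 univariate scaling, subtraction heatmaps
    with mean +/- SD relevance filtering, interval kinetics, hierarchical
    clustering, patient-versus-control integration, and leave-one-out
    multi-classifier prediction of coagulation-pathway interventions. A
    synthetic-data generator with exact ground truth makes every stage testable
    without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    pracma,
    igraph,
    EBImage,
    tiff,
    stats,
    utils,
    MASS,
    e1071,
    rpart,
    randomForest,
    nnet,
    class
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
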