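Package: vesseltort
Title: Vessel Centerline Tortuosity and In-Stent Stenosis Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the three-dimensional tortuosity of vessel segments
    from discrete centerline points or tubular surface meshes and models its
    association with in-stent stenosis after flow-diverter stenting. Fits
    free-knot regression splines to centerline points, computes Frenet-Serret
    curvature and torsion profiles and the distance-metric (DM) tortuosity
    index, extracts centerlines from tubular meshes by maximal-inscribed-circle
    cross-sections, quantifies percent in-stent stenosis, and provides the
    downstream analysis stage: univariate screening, collinearity filtering,
    multivariable logistic regression with odds ratios, ROC evaluation, and a
    machine-learning benchmarking protocol (z-scoring, borderline-SMOTE,
    recursive feature elimination, cross-validated grid search). Ships a
    synthetic-data generator for centerlines, tubular meshes and patient
    cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    e1071,
    jsonlite,
    glmnet,
    pROC,
    ranger,
    testthat (>= 3.0.0),
    xgboost
Config/testthat/edition: 3
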