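Package: bcsdeform
Title: Predicting Breast Shape Deformation After Breast-Conserving Surgery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Machine-learning prediction of the post-surgical breast shape
    after breast-conserving surgery from paired pre-/post-surgery point
    clouds. Provides a synthetic paired point-cloud generator emulating
    wound-healing contraction around a cylindrical excision volume, breast
    quadrant and excision-cylinder geometry, per-point feature engineering
    (coordinates, signed and Euclidean distances to the excision cylinder,
    cylindrical coordinates, and clinical one-hot factors), per-axis random
    forest displacement regression with optional adaptive instance
    weighting, gradient-boosting and multi-output comparators, a
    per-quadrant heuristic baseline, and pair-wise and bidirectional
    nearest-neighbour distance evaluation under leave-one-patient-out
    splits.
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
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
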