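Package: gaitfatigue
Title: Free-Living Gait Analysis and Fatigue Association from Lower-Back Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to derive macro (activity-level) and micro (step-level) gait
    characteristics from raw lower-back triaxial accelerometer recordings in
    free-living conditions, pool them over the two-hour windows preceding
    momentary patient-reported fatigue scores, and relate them to physical and
    mental fatigue. Includes walking-bout detection from windowed
    acceleration thresholds, wavelet-based initial/final contact detection,
    inverted-pendulum step length estimation, power-law and lognormal
    bout-length summaries, per-feature binomial mixed-effects screening with
    marginal and conditional R-squared, and low/high fatigue classification
    under intersubject and intrasubject cross-validation with SMOTE
    rebalancing, grid-searched classifiers, and two feature-importance
    rankers. A synthetic cohort generator with full ground truth supports
    validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    lme4,
    pracma,
    purrr,
    randomForest,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
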