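Package: sleepmos
Title: Hybrid LSTM and Metaheuristic-Optimised SVM Modelling of Sleep Quality from Wrist Actigraphy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Objective sleep-quality prediction from epoch-level wrist actigraphy.
    Implements a hybrid pipeline: preprocessing of one-minute activity counts
    (off-wrist trimming, forward fill, hourly downsampling, sliding 24-hour
    windows, min-max normalisation), Cole-Kripke style sleep/wake scoring with
    nightly summaries, two composite targets (a weekly sleep-quality score on a
    0-12 PSQI-style scale with three classes, and a sleep-consistency score
    combining duration variability, weekday-weekend midpoint shift and midpoint
    variability with four classes), deep temporal features from a stacked LSTM
    implemented in the package, hand-crafted statistical features, dual
    metaheuristic wrapper feature selection (genetic algorithm and geometric,
    velocity-free binary particle swarm optimisation) combined by union, linear
    support-vector-machine classification with grouped stratified
    cross-validation, ablation variants, and permutation feature importance.
    A seeded synthetic actigraphy generator with known nightly ground truth
    makes the whole pipeline testable without access-restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    e1071,
    pROC,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    xgboost,
    optparse
Config/testthat/edition: 3
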