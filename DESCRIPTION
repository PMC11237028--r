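Package: nfabt
Title: Fuzzy Basis-Function Alarming for Blood-Transfusion Requirement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying a fuzzy basis-function (FBF) alarming system for
    packed-red-blood-cell transfusion need in blood-cancer patients. Includes a
    synthetic electronic-health-record cohort generator calibrated to published
    summary statistics (98 patients, 61 demographic, clinical and laboratory
    features, daily trajectories, ~7% daily transfusion prevalence), a
    preprocessing pipeline (high-missingness exclusion, missingness indicators,
    median imputation, categorical encodings, first-timepoint anchoring,
    normalization, Pearson correlation screening), a triangular-membership FBF
    inference core with Wang-Mendel rule learning and swarm-distributed
    evaluation, an additive-white-Gaussian-noise robustness harness, and a
    cross-validated sequence-classifier benchmark (LSTM, bidirectional LSTM,
    boosted and bagged ensembles, bagged nearest neighbours, multilayer
    perceptron).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    nnet,
    class,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
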