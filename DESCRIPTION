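Package: eegstress
Title: Time-Domain EEG Stress Classification with Segmentation Schemes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for classifying perceived stress from
    multichannel EEG recordings using time-domain analysis. Recordings are
    split into non-overlapping or overlapping (sliding) windows, 20
    time-domain descriptors are computed per electrode and window, subjects
    are labeled stressed or non-stressed by thresholding Perceived Stress
    Questionnaire scores at the cohort mean plus or minus half a standard
    deviation, features are ranked by information gain, and five standard
    classifiers are compared under 10-fold cross-validation with a unified
    evaluation report including the Golden Distance score. A synthetic
    cohort generator with a planted, tunable class effect makes every stage
    testable end to end without access to the original recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ranger,
    rpart,
    nnet,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
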