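Package: wristldct
Title: Predicting the Levodopa Challenge Test from Wrist-Worn Sensor Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for estimating the levodopa response of people with
    Parkinson's disease from ambulatory wrist-sensor recordings.
    Bradykinesia and tremor scores logged every two minutes over a
    multi-day recording are turned into moving-percentile features around
    the first daily levodopa dose; a bank of five threshold logistic
    classifiers maps features to a six-level ordinal motor-function
    severity scale; and per-subject dose-time versus effect-time severity
    differences emulate the clinical levodopa challenge test. Includes a
    synthetic cohort generator with known ground truth, k-nearest-neighbour
    mutual-information feature selection with joint-mutual-information
    ranking, subject-grouped evaluation with ROC and precision-recall
    statistics, and exclusion heuristics for subjects who are already ON,
    in an uncertain response zone, or show excess day-to-day variability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    xgboost
Config/testthat/edition: 3
RoxygenNote: 7.3.3
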