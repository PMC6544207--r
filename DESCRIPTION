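Package: oculofatigue
Title: Oculometrics-Based Fatigue Detection and Micro-Break Biofeedback
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Toolkit for detecting acute fatigue during computer work from
    eye-tracking recordings. Transforms raw gaze and pupil sample streams
    into validated ocular events (blinks, saccades, fixations), computes a
    32-feature oculometric summary per task segment (blink dynamics,
    PERCLOS, pupillometry, fixation dispersion, saccadic main sequence),
    trains a label-noise-robust boosted decision-tree classifier of
    fatigued versus alert segments with leave-one-person-out
    cross-validation, sequential floating forward feature selection under a
    Youden-index criterion, and permutation testing against chance, and
    drives a micro-break biofeedback session state machine. Includes a
    synthetic gaze generator with ground-truth events and fatigue structure
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
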