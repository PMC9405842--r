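Package: oculodex
Title: Binocular Disconjugacy Analysis and Dyslexia Screening from Eye-Tracking Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing binocular horizontal eye-tracking recordings.
    Implements the Disconjugacy Global Index (DGI): detection of micro-segments
    during which the two eyes move in opposite directions, identified from the
    sign of the product of the two eyes' instantaneous velocities, split by the
    sign of the left-minus-right disparity signal and filtered by a minimum
    dwell of three samples. Also provides velocity-threshold saccade and
    fixation descriptor extraction (amplitude, duration, peak and average
    velocity, post-saccadic disconjugate drift over 80 and 160 ms windows,
    fixation duration) with mean/SD/CV/N aggregation, a calibrated synthetic
    binocular free-viewing simulator with ground-truth disconjugate events, and
    a cross-validated SVM / ridge-logistic classification pipeline with
    Mann-Whitney group statistics and permutation feature importance, aimed at
    oculomotor screening studies of dyslexia.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
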