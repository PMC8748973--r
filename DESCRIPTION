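Package: biozbp
Title: Cuffless Blood Pressure Estimation from Wrist Bio-Impedance Sensor Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal-processing and modelling pipeline for calibration-free
    cuffless blood pressure (BP) monitoring from a wrist-worn bio-impedance
    (Bio-Z) sensor array. Reconstructs the hidden arterial pulse from six
    Bio-Z channels with a linear convolutional autoencoder, detects the six
    characteristic points of each heartbeat (diastolic peak, maximum slope,
    systolic foot, inflection point, dicrotic peak and notch), extracts
    morphology features (time, amplitude, area, dicrotic and amplitude
    histogram families), and maps them to systolic and diastolic BP with
    per-subject AdaBoost.R2 regression over depth-limited trees. Includes a
    synthetic multi-channel Bio-Z generator with known source pulse,
    location-dependent sensor transfer functions and BP trial profiles, plus
    evaluation protocols (20-fold contiguous cross-validation,
    leave-one-trial-out, cross-location testing) and British Hypertension
    Society grading.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    rpart,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
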