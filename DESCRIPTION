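Package: fogcast
Title: Freezing-of-Gait Prediction from Wearable Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting freezing of gait (FOG) in Parkinson's
    disease from body-worn inertial measurement units (IMUs). Provides a
    synthetic multi-IMU gait simulator with annotated pre-freeze and freeze
    episodes, signal cleaning and sliding-window segmentation, a bank of 22
    time- and frequency-domain features per channel, Taguchi L16(4^3)
    orthogonal-array optimization of the feature-extraction hyperparameters
    with main-effect, interaction and LogWorth analysis, a random-forest
    pre-freeze classifier evaluated under leave-one-patient-out
    cross-validation, and episode-based evaluation (hit rate, false-positive
    rate, mean prediction time).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    ranger,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
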