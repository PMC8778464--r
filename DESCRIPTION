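Package: pigdsense
Title: Thigh-Worn IMU Gait Analysis and PIGD Score Regression
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Processing pipeline for single thigh-worn inertial measurement
    unit recordings of the timed-up-and-go (TUG) test in Parkinson's disease:
    Kalman-filter thigh pitch estimation, zero-lag Butterworth filtering,
    continuous-wavelet-transform walking-bout detection, stride segmentation,
    a 102-feature time/frequency gait descriptor set, and support vector
    regression of the postural instability/gait difficulty (PIGD) score with
    nested leave-one-subject-out hyperparameter optimization. Includes a
    synthetic TUG recording generator with ground-truth gait events for
    testing every stage without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    quadprog,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
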