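Package: pfmg
Title: Force-Myography Gesture Recognition and Infrared Teleoperation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: End-to-end pipeline for pneumatic force-myography (pFMG) armband
    gesture recognition and infrared device teleoperation. Provides a seeded
    synthetic signal generator for five-channel pressure streams with optional
    IMU Euler orientation, sliding-window segmentation with signal integrity
    checks, seventeen time-domain features (RMS, IAV, SSI, VAR, the MAV
    family, and others), coefficient-of-variation feature ranking and
    selection, a trial-segregated combinatorial cross-validation harness over
    seven classifier families, mode-vote post-processing with an Unknown
    rejection class and state-change debouncing, quasi-dynamic spatial
    augmentation with proportional control from Euler-angle deltas, and a
    software model of NEC infrared code recording, gesture mapping, and
    simulated transmission.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    caret,
    e1071,
    jsonlite,
    randomForest,
    rpart,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
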