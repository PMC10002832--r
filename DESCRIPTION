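Package: oscilloclip
Title: Oscillometric Blood Pressure Estimation from a Spring-Loaded
    Pinhole Finger Clip
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for cuffless oscillometric blood pressure
    estimation with a spring-loaded pinhole clip pressed by a fingertip
    against a smartphone camera. The clip encodes the applied finger force
    in the size of the pinhole projection and the photoplethysmogram (PPG)
    in its brightness. The package decodes both signals from 8-bit
    grayscale frames (histogram equalization, intensity-threshold area
    measurement, constrained-mean PPG), drives a guided 20-level
    force-ladder protocol as a headless state machine (+/-2% tolerance,
    2 s hold, 5 s record, restart on excursion), assembles the subsampled
    blood-volume oscillogram from band-passed per-level PPG via averaged
    peak prominence, and estimates systolic and mean blood pressure with
    L1-penalized regression on the normalized 18-point oscillogram
    (diastolic by linear regression on the two predictions), evaluated
    with leave-two-out cross-validation, MAE/bias and Bland-Altman
    summaries. A physics-grounded simulator (pinhole projection geometry,
    transmural-pressure-dependent pulse envelope, compliant-but-imperfect
    user model) stands in for the hardware so every stage is testable
    without human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    graphics,
    signal,
    glmnet,
    jsonlite,
    png,
    MASS
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
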