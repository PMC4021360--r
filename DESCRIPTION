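Package: diveoptim
Title: Optimal Swim Speed, Drag and Buoyancy Analysis for Diving Biologgers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing swim speed in breath-hold divers under
    manipulated drag and buoyancy, built around controlled dive trials with
    harness-mounted accelerometers and depth loggers. Provides readers and
    writers for mixed-rate (1 Hz depth, 32 Hz acceleration) trial records,
    pitch estimation from longitudinal acceleration, descent/ascent phase
    segmentation, pitch-corrected swim speed, a cost-of-transport model with
    a closed-form optimal swim speed, composite drag coefficients for
    instrument attachments, buoyancy/ballast arithmetic from body
    composition, mixed-model AIC selection of speed covariates, and a
    synthetic-data generator that emulates the experimental design for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
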