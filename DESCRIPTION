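Package: capsnav
Title: Magnetic Capsule Endoscope Actuation and Localization Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation toolkit for actively controlled magnetic
    capsule endoscopy. Models a ten-coil electromagnetic actuation (EMA)
    system (Biot-Savart coil fields, actuation matrix, minimum-norm current
    allocation, yaw/pitch/force command mapping), recovers the capsule
    magnet's 5-DOF pose from a mono-axis Hall-sensor array using external
    field compensation and Levenberg-Marquardt nonlinear least squares, and
    closes the loop in a quasi-static trajectory-tracking simulator with a
    synthetic sensor-frame generator (noise plus ADC quantization).
    Experiment presets reproduce free-space U-shape tracking trials with
    per-trial error statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    pracma
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    MASS,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
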