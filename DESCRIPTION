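Package: curladapt
Title: Simulation and Analysis of Bimanual Curl-Field Adaptation Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for force-field adaptation experiments in which a
    velocity-dependent curl field applied to one hand is driven by the
    velocity of the other hand. Builds the three-phase, block-randomized
    trial schedule; simulates synthetic participants (minimum-jerk reach
    kinematics with motor noise, coupled curl-field and force-channel
    dynamics, a single-rate adaptive learner with a configurable
    bimanual encoding weight); conditions channel-trial force recordings
    (zero-phase Butterworth filtering, drift correction, peak-velocity
    alignment); computes adaptation metrics (force compensation, maximum
    perpendicular error, peak forces); and fits four hand-velocity
    encoding models by least squares with BIC model comparison,
    generalization predictions and unimanual-transfer predictions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
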