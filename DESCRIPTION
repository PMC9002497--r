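Package: moveletr
Title: Personalized Activity Recognition from Smartphone Accelerometer and
    Gyroscope Data with Multistream Movelets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the movelet method for personalized human activity
    recognition from smartphone sensor data: per-participant dictionaries of
    one-second windows ("movelets") of tri-axial accelerometer and gyroscope
    measurements, nearest-dictionary classification under per-axis Euclidean
    discrepancy metrics for single-sensor (accelerometer-only, gyroscope-only)
    and joint-sensor modes, majority-vote label smoothing, and
    confusion-matrix evaluation with activity-group accuracy summaries.
    Includes linear-interpolation synchronization of gyroscope samples to the
    accelerometer timestamp grid, a synthetic signal generator emulating the
    characteristic accelerometer and gyroscope signatures of everyday
    activities (standing, sitting, walking, stair climbing, postural
    transitions), and a command-line interface over the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
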