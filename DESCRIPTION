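Package: imuperf
Title: Instrumented Chair-Stand and Timed Up-and-Go Analysis from a Lumbar
    Inertial Sensor
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates, segments and analyses 30-second Chair Stand (30CST)
    and Timed Up and Go (TUG) tests recorded by a smartphone inertial
    measurement unit worn at the fifth lumbar vertebra. Provides a
    reproducible synthetic-cohort generator, subphase segmentation of
    postural transitions, turns and walking, movement-quality features
    (durations, root-mean-square intensity, normalized jerk scores, turn
    kinematics, step counts), and a screened stepwise logistic pipeline
    that discriminates High from Very High Functional Status by the
    Late-Life Function and Disability Instrument median split, with
    DeLong comparison of correlated AUCs and bootstrap optimism-corrected
    internal validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
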