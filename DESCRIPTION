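Package: frailtymouse
Title: Composite Frailty Assessment for Longitudinal Mouse Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Scores and classifies frailty in longitudinal preclinical mouse
    cohorts by combining a 27-item deficit-accumulation frailty index with a
    Fried-style physical frailty phenotype. Reduces raw phenotype trials
    (rotarod walking speed, grip strength, treadmill endurance, voluntary
    wheel activity) and weekly body weights to six per-animal criterion
    values, derives sex-specific 20th-percentile cutoffs from the Old group
    at baseline, tallies positive frailty markers into robust, prefrail and
    frail categories, and tracks category transitions between baseline and
    endpoint. Includes a calibrated synthetic cohort generator so the whole
    pipeline is testable without animal data, validated CSV input/output for
    every table, and an end-to-end reporting driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
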