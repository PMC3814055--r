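Package: radvol
Title: Tumor Volume Regression Modelling for Fractionated Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and fits tumor volume changes during fractionated
    radiotherapy using a modified linear-quadratic cell-survival model with
    two correction factors and a simplified two-compartment (viable and
    lethally damaged) cell-population model. Provides forward simulation of
    volume trajectories under arbitrary fractionation schedules, least-squares
    estimation of the correction factors from measured volume time series,
    goodness-of-fit scoring against the conventional linear-quadratic
    comparator, a synthetic-cohort generator for parameter-recovery studies,
    and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
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
RoxygenNote: 7.3.3
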