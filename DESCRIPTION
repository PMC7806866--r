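Package: radcycle
Title: Compartmental Cell-Cycle Kinetics and Radiation-Induced Perturbations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic compartmental model of cell-cycle progression with
    four phases (G1, S, G2, M) and an age-structured S-phase delay line,
    evolved by a finite-difference transition matrix. Includes calibration of
    transition rates from flow-cytometry phase percentages (Steel's formulas
    for mean phase durations, exponential growth-curve fitting, chi-square
    minimisation against steady-state phase fractions), piecewise-constant
    transition-rate schedules describing radiation-induced G2 and G1 arrest,
    reconstruction of DNA-content histograms by Gaussian superposition, and a
    seeded synthetic-data generator emulating flow-cytometry time courses.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
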