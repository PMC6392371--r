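Package: lizgrowth
Title: Growth Ecology from Capture-Recapture Body-Size Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing individual growth from mark-recapture body-size
    records of lizards (or other indeterminate growers measured by snout-vent
    length). Converts repeated captures into per-individual growth-rate
    increments, fits and compares three classical growth laws (Von Bertalanffy,
    logistic-by-length, logistic-by-weight) by nonlinear least squares on the
    rate-versus-length relationship, integrates the selected law into a growth
    curve anchored at hatchling size, estimates age at sexual maturity,
    summarises growth by sex, age class, season and year, and correlates
    monthly growth with prey availability and climate. Includes an
    individual-based simulator of the underlying capture-recapture study design
    for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
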