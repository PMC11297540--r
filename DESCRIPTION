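Package: dxinterval
Title: Diagnostic Interval Construction and Income-Inequality Analysis
    for Cancer Registry and Claims Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs cancer diagnostic intervals from linked
    administrative encounter data: category-specific lookback windows
    derived by statistical process control on pre-diagnosis encounter
    frequency profiles, referring-physician linkage for procedure-based
    encounters, and earliest-eligible-encounter selection.  Classifies
    nine diagnostic pathways (screen-detected versus symptomatic, with
    and without emergency-department presentation), produces stratified
    descriptive tables, and estimates neighbourhood-income-quintile
    inequalities in the conditional 50th and 90th percentile diagnostic
    interval by quantile regression with pair-bootstrap confidence
    intervals.  Ships a synthetic generator of linked registry, person,
    eligibility and encounter tables with ground-truth labels so the
    whole pipeline is testable without access-restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    yaml,
    generics,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    quantreg,
    optparse,
    withr
Config/testthat/edition: 3
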