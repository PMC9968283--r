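Package: tslinkage
Title: Fast Privacy-Preserving Record Linkage for Patient Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic record linkage for time-series patient data, where
    records are matched on a handful of raw (timestamp, value) readings
    sampled from each series instead of quasi-identifiers. Provides a
    quadratic nested-scan matcher and an equivalent sort-merge matcher with
    near-linear complexity, a synthetic ergometric heart-rate simulator
    (three-phase piecewise-linear envelope plus noise), key projections and
    value transforms for studying how dropping timestamp components degrades
    linkage accuracy, a closed-form model for the expected number of chance
    matches, and a pseudonymize-minimize-sample-verify workflow for releasing
    time-series data with the bare minimum of identifying information.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
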