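Package: pathmeander
Title: Indirect Quantification of Path Meander from Trap-Grid Catch Decay
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates correlated random walkers moving through grids of
    absorbing traps, fits the exponential decay constant (k) of catch across
    edge traps after a corner release, builds a simulation-derived standard
    curve relating k to the circular standard deviation (c.s.d.) of turn
    angles, and inverts measured decay constants from field trapping grids
    into estimates of path meander with uncertainty. Includes capture-rate
    sweeps across c.s.d. for high- and low-density target scenarios and
    generators for synthetic field-style catch tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    readr,
    generics,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
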