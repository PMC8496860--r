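Package: galswitch
Title: Bistability and Natural Variation in Yeast GAL Pathway Induction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mechanistic modelling of galactose-pathway induction in budding
    yeast under mixed glucose/galactose conditions. Provides an ordinary
    differential equation model of the GAL regulatory network with
    competitive sugar transport, steady-state bimodality classification
    over sugar grids, decision-front extraction, Metropolis-Hastings
    parameter calibration against strain induction tables, a
    parameter-perturbation survey of bimodal-range shifts, single-parameter
    phenotype-switching scans, and a synthetic strain-table generator for
    fully reproducible analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
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
NeedsCompilation: yes
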