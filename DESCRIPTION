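Package: spclone
Title: Single-Progenitor Clonal Dynamics in Squamous Epithelia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and inference tools for stochastic clonal dynamics
    in stratified squamous epithelia such as mouse esophagus and
    interfollicular epidermis. Implements exact non-Markovian Monte Carlo
    simulation of competing cell-fate models (single progenitor,
    stem/committed-progenitor hierarchies, two stem-cell populations) with
    arbitrary cell-cycle time distributions, H2B-GFP label-dilution
    modeling with modality testing and division-rate inference, and
    maximum-likelihood estimation of progenitor parameters from
    lineage-tracing clone-size distributions, together with synthetic-data
    generators that emulate both experimental designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    stats,
    utils,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
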