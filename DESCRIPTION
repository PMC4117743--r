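Package: csac
Title: Constrained Self-Avoiding Chromatin Chains Under Nuclear Confinement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates equilibrium ensembles of coarse-grained chromatin
    fibers as self-avoiding bead chains grown inside a spherical nuclear
    confinement by geometric sequential importance sampling (Rosenbluth
    weighting), and analyses them with the observables used in chromosome
    organisation studies: mean-square spatial distance and contact
    probability scaling exponents with bootstrap confidence intervals,
    plateau (leveling-off) detection, conformational clustering,
    detection of highly interactive domain-like substructures, and
    Boltzmann reweighting under randomly placed binder sites.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
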