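Package: tiplink
Title: Kinetics and Force Spectroscopy of the Hair-Cell Tip-Link Connection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Kinetic modelling and data analysis for single-molecule force
    spectroscopy of the double-stranded PCDH15-CDH23 tip-link connection.
    Implements Bell-Evans slip-bond kinetics, a multi-state force-dependent
    avidity model with elastic modulation of rebinding, rupture-force mode
    estimation by kernel density, worm-like-chain fitting of force-extension
    traces, chi-square model fitting with curvature-based parameter errors,
    biolayer-interferometry sensorgram kinetics, and a Monte Carlo simulator
    of tip-link lifetime under oscillatory hair-bundle stimulation.  A
    synthetic-data generator emulates every instrument input so the full
    analysis chain is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
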