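Package: evcapture
Title: Monte Carlo Simulation of Extracellular Vesicle Capture in
    Micropillar Immunoaffinity Beds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and simulating microfluidic
    immunoaffinity devices that enrich extracellular vesicles (EVs) on
    antibody-coated micropillar arrays. Provides a stochastic particle
    tracker combining plane-Poiseuille convection, Brownian diffusion and
    receptor-ligand forward-rate binding kinetics to predict EV recovery
    as a function of volumetric flow rate, together with deterministic
    design calculators (internal surface area, monolayer EV load
    capacity, antibody coverage, throughput and processing time) for
    multi-bed pillar devices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
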