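Package: finitehost
Title: Neutral Microbiome Colonization of Hosts with Finite Lifespans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic modelling of microbiome assembly in initially
    microbe-free hosts whose lifespans are finite and geometrically
    distributed. Provides an individual-based simulator of the nearly-neutral
    death-birth-immigration process within hosts, an exact master-equation
    solver for the marginal within-host frequency distribution of a focal
    taxon (a birth-death chain augmented with resetting to the microbe-free
    state at host death), the drift and diffusion coefficients of the
    matching Fokker-Planck approximation, and the summary layer used to
    interrogate the model: total-variation differences between finite- and
    infinite-lifespan predictions, colonization probabilities, modality
    classification of stationary distributions (alternative microbiome
    states), lifespan-weighted sampling of simulated trajectories, and
    reproducible (migration, host-turnover) parameter sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    methods,
    parallel,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
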