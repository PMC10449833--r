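Package: spikevar
Title: Trial-to-Trial Variability in Spiking Cortical Microcircuit Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates a conductance-based spiking network of one excitatory
    and three inhibitory interneuron populations (PV, SST, VIP) built from
    adaptive exponential integrate-and-fire neurons, estimates the network's
    multi-dimensional neuron transfer-function on a lattice of evoked input
    rates with trilinear interpolation, and propagates trial-to-trial input
    distributions (mean, balance, and covariance of per-trial input rates)
    to the across-trial variability of the population output rates, both
    through the interpolated transfer-function and by direct multi-trial
    network simulation. Includes generators for Poisson input drive and
    multivariate-normal trial clouds, broom-style tidiers, and ggplot2
    visualisations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    MASS,
    generics,
    graphics,
    utils,
    deSolve,
    ggplot2,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    knitr
Config/testthat/edition: 3
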