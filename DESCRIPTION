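Package: cbsim
Title: Tile-Based Spiking Network Simulation of the Cerebellar Microcircuit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and simulates layered-sheet tile models of the cerebellar
    microcircuit with conductance-based leaky integrate-and-fire neurons,
    alpha-function synapses, two-dimensional Gaussian and parallel-fiber
    (orthogonal-cross) wiring kernels, and forward-Euler integration at a fixed
    0.1 ms step with per-tile scheduling and neighbor (halo) spike bookkeeping.
    Ships a complete declarative default model of one square millimeter of
    cerebellar cortex plus pontine and olivary afferents, turnkey resting-state,
    constant-drive and optokinetic-response (OKR) protocols, and analysis tools:
    population firing rates, spike rasters, exponentially filtered activity
    traces, the population similarity index, and cosine fits of modulated
    firing rates.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
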