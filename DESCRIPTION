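Package: spikecoding
Title: Efficient-Coding Spiking Networks with Synaptic Delays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of leaky integrate-and-fire networks whose
    connectivity and dynamics are derived from a signal-reconstruction loss
    (predictive / efficient spiking coding). Implements the idealized
    instantaneous-synapse network and its Dale's-law excitatory/inhibitory
    variant with continuous synaptic dynamics and transmission delays,
    together with the analyses that characterise the efficient-coding regime:
    leaky spike-train decoding, reconstruction error and bias, bias-nulling
    cost calibration, inter-spike-interval statistics, multitaper population
    spectra and spectrograms, voltage correlation and coherence,
    excitatory/inhibitory current balance diagnostics, Poisson rate-model
    baselines, signal-detection discrimination, and parameter sweeps over
    noise, synaptic reliability, network size and synaptic time constants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
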