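Package: armnet
Title: Active-Refractory Markov Models of Balanced Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and analysis of the population dynamics of balanced
    random networks of excitatory and inhibitory spiking neurons. Provides a
    fixed in-degree leaky integrate-and-fire network simulator, reconstruction
    of the mean-field flow and of the state-dependent (self-generated) noise
    from binned population spike counts, a two-state Active-Refractory Markov
    (ARM) population model with a binomial stochastic implementation and its
    deterministic mean-field equations, nonlinear least-squares estimation of
    the ARM transition rates from reconstructed flows, empirical Markov-chain
    analysis of count time series with spectrum-based bin-size selection,
    discrete-aware log-normal spike-count fits, correlation and spectral
    statistics, the stationary Fokker-Planck membrane-potential density of the
    integrate-and-fire neuron, and a static transfer-function rate-model
    baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    deSolve,
    minpack.lm,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
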