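Package: astroud
Title: Neuron-Astrocyte Network Models of Cortical Up-Down Dynamics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulators and analysis tools for three-population models of
    cortical Up-Down state switching in which astrocytes modulate network
    bistability through gliotransmission.  Provides a rectified-linear
    firing-rate model with spike-frequency adaptation and Ornstein-Uhlenbeck
    external drive, a stochastic spiking network of leaky integrate-and-fire
    neurons coupled to threshold-release astrocytes with population synaptic
    variables and transmission delays, analytic fixed-point and linear
    stability analysis of the rate model, diffusion-approximation mean-field
    analysis with saddle-node bifurcation sweeps for the spiking network, and
    automatic threshold-based segmentation of population activity into Up and
    Down phases with duration statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
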