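Package: v1net
Title: Emergent Attractor Dynamics and Receptive Fields in a Spiking Model of Developing V1
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates a small patch of developing primary visual cortex as a
    network of adaptive exponential integrate-and-fire neurons (100 excitatory,
    20 inhibitory) in which feedforward and lateral excitatory synapses follow a
    voltage-dependent spike-timing-dependent plasticity rule with
    weight-dependent potentiation and a slow homeostatic trace. Driven by
    difference-of-Gaussian filtered naturalistic image patches split into
    ON/OFF channels, the network jointly develops orientation-selective
    receptive fields and sparse, bidirectional lateral connectivity supporting
    fast attractor dynamics. Includes a synthetic 1/f image generator, the
    training/testing/spontaneous-activity protocols, network manipulations
    (inhibition silencing, lateral ablation, spike blocking), stimulus-mixture
    morphing experiments, and the connectivity and firing-rate analyses, with
    tidy tabular outputs and ggplot2 visualisations.
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
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
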