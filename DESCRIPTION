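Package: procode
Title: Prospective Coding in Two-Compartment Spiking Neurons
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of prospective coding in two-compartment
    (dendrite plus soma) spiking neurons. Implements the conductance-based
    somatic integrator with a point dendrite, a differential-Hebbian synaptic
    plasticity rule whose potentiation window is a low-pass filtered
    postsynaptic potential, and the analytic fixed-point theory that links the
    learned dendritic rate to the expected future discounted somatic input
    rate, including the correspondence with temporal-difference learning
    TD(lambda) on latent Markov chains. Ships seeded generators for
    deterministic, frozen-Poisson, inhomogeneous-Poisson and
    Ornstein-Uhlenbeck-driven presynaptic activity, and end-to-end experiment
    runners for anticipatory firing ramps, delayed paired-associate readouts,
    time-series advancement and compressed sequence replay in recurrent
    networks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
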