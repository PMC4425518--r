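Package: axonet
Title: Electrically Coupled Unmyelinated Axon Networks of Brainstem Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Biophysical simulation of a rostrocaudal column of brainstem
    reticulospinal interneurons (dINs) whose thin unmyelinated axons are
    electrically coupled by axo-axonic gap junctions. Provides
    multicompartment cable morphologies, Hodgkin-Huxley sodium and potassium
    kinetics with a Goldman-Hodgkin-Katz calcium current, stochastic
    gap-junction layout generation, sparse passive steady-state analysis of
    coupling coefficients, a compiled implicit integrator for active network
    dynamics, measurement protocols (input resistance, firing classification,
    rebound, action-potential propagation and conduction velocity, population
    pacemaker firing), and a stochastic sensory-interneuron drive model for
    population recruitment experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
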