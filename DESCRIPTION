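Package: cxring
Title: Spiking Ring-Attractor Model of the Insect Head-Direction Circuit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Reverse-engineers the protocerebral-bridge / ellipsoid-body
    head-direction circuit of the fruit fly into an effective eight-fold ring
    network and simulates it as a spiking leaky integrate-and-fire ring
    attractor. Provides the innervation table of the four neuron classes
    (E-PG, P-EG, P-EN, Delta7), synapse inference from terminal overlap,
    iterative reduction to effective units, a fast spiking network simulator
    with action-potential templates and postsynaptic-current kernels,
    retinotopic von Mises / Poisson heading-stimulus encoding, population
    vector bump decoding, synaptic-weight optimization (particle swarm and
    simulated annealing), a synthetic fly-like trajectory generator, and
    noise-sensitivity / lesion sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
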