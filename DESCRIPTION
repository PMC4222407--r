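Package: l5sim
Title: Biophysical Simulation and Excitability Analysis of Layer 5 Pyramidal
    Neurons Under Neuromodulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Multi-compartment conductance-based simulation of a neocortical
    layer 5 pyramidal neuron, with a library of Hodgkin-Huxley-style channel
    models including a BK channel gated jointly by voltage and intracellular
    calcium, spatial conductance-density rules for soma, axon and dendrites,
    and an implicit cable-equation integrator for current- and voltage-clamp
    protocols. Includes tools to screen channel modulations (such as protein
    kinase C activation modelled as conductance scalings and a persistent
    sodium half-activation shift), to extract excitability features (rheobase,
    F-I gain, input resistance, after-hyperpolarization amplitude, action
    potential voltage threshold) from current-clamp trace families, to
    generate synthetic paired control/treatment cohorts of such features, and
    to run the paired statistical comparisons used on them.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
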