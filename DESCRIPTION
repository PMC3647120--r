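Package: dendshunt
Title: Dendritic Shunting Inhibition in Neuron and Network Models
Version: 0.1.0
Authors@R:
    person("Maintainer", "dendshunt", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models of multiplicative dendritic integration by shunting
    inhibition. Implements a three-compartment conductance-based neuron
    (soma plus two dendritic sites) with an exact steady-state solver and
    empirical shunting-strength extraction; reduced single-compartment
    models in which excitatory and inhibitory somatic responses combine
    through a multiplicative rule with a closed-form shunting strength,
    for on-path, out-of-path, multi-branch and global (peri-somatic)
    synaptic geometries; spike-driven exponential synapse dynamics; a
    recurrent excitatory/inhibitory spiking network in which inhibitory
    neurons act as global shunting gates and which sustains low-rate
    persistent activity; and the corresponding rate-based mean-field
    fixed-point and linear stability analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
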