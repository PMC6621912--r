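Package: deeplsm
Title: Deep Liquid State Machines with Neural Plasticity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation of deep liquid state machines: stacks of randomly
    connected spiking reservoirs of leaky integrate-and-fire neurons,
    interleaved with winner-take-all encoding layers trained by trace-based
    spike-timing dependent plasticity with synaptic scaling and intrinsic
    homeostasis, and read out through a two-stage (deep + spatial) attention
    network. Includes distance-dependent 3-D grid connectivity, short-term
    synaptic plasticity, synaptic-trace state filtering, an analytic model of
    synapse counts, multiplication counts, weight memory and energy for
    deep-LSM, LSM and LSTM architectures, and a synthetic generator of labeled
    multivariate feature sequences for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    MASS
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
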