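Package: mixedsyn
Title: Simulation and Analysis of Mixed Electrical-Chemical Synaptic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates small spinal motor circuits of spherical integrate-and-fire
    somata coupled by non-rectifying gap junctions (absolute conductances in nS)
    and surface-area-scaled chemical synapses, including the size-graded
    convergence networks in which electrical-synapse number grows with motor
    neuron soma diameter. Provides the virtual current-clamp protocols
    (hyperpolarizing steps, single-spike PSPs, coupling maps, convergence
    sweeps), whole-cell sweep analysis (input resistance, weighted
    double-exponential time constants, PSP amplitudes, synaptic failure
    classification and electrical-template subtraction, ohmic currents, fictive
    swim peak currents), rank-based statistics with exact small-sample p-values,
    and a seeded generator of synthetic recordings with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
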