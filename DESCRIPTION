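Package: v1micro
Title: Multi-Column Spiking and Rate Models of Mouse V1 Microcircuits with
    PV, SST and VIP Interneurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for simulating contextual visual processing in mouse
    primary visual cortex with cell-type-specific inhibition. Provides a
    four-population (pyramidal, PV, SST, VIP) Wilson-Cowan-type firing-rate
    model with steady-state enumeration, stability classification and
    input scans; a builder for layered cortical columns and one-dimensional
    multi-column networks with cell-type-specific superficial-layer
    connectivity; a clock-driven leaky integrate-and-fire simulation engine
    with multiple exponentially decaying postsynaptic-current channels;
    stimulus protocols (thalamic pulse, figure-ground, two-object, top-down
    modulation); and analysis utilities for population rates, PSTHs,
    edge-normalized column profiles, onset latencies and oscillation
    frequency.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
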