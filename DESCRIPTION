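Package: fsiephys
Title: Intracellular Electrophysiology Analysis and Simulation for Fast-Spiking Interneurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Feature extraction for whole-cell patch-clamp recordings of
    cortical fast-spiking interneurons (spike threshold by dV/dt, rheobase,
    first-spike latency regimes, phase plots, passive membrane properties,
    spontaneous-event detection, bi-exponential EPSC decay with weighted time
    constant, and GluN2B/ifenprodil block quantification), together with a
    conductance-based single-compartment simulator with a Kv1-like D-type
    potassium current and AMPA/NMDA synapses that generates matched "vehicle"
    and "mk801" phenotype cohorts for end-to-end pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    minpack.lm,
    pracma,
    jsonlite,
    yaml,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
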