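Package: deltacircuit
Title: Biophysical Layer-V Cortical Network Modelling of Delta Oscillations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Conductance-based multicompartment modelling of a layer-V
    cortical microcircuit (pyramidal cells, large basket cells and
    neurogliaform cells) for studying delta-band oscillations. Provides
    Hodgkin-Huxley-style channel and dual-exponential synapse mechanisms,
    a fixed-step implicit compartmental integrator, ball-and-stick
    morphology reduction by f-I curve fitting, network construction with
    GABA_A/GABA_B receptor blockade switches, spike-train spectral band
    power analysis, grid-search calibration of synaptic conductances,
    mapping of schizophrenia-associated gene-expression ratios onto ion
    channel conductances, a synthetic expression-data generator, and the
    simulation experiments and Mann-Whitney statistics built on them.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
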