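Package: megnet
Title: Multi-Frequency Sensor-Level MEG Functional Connectivity Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis of sensor-level magnetoencephalography
    (MEG) resting-state functional connectivity across seven frequency
    bands (0.1-250 Hz).  Provides a synthetic cohort generator with 1/f
    background noise and planted band-limited regional couplings,
    zero-phase Butterworth band decomposition, signed Welch-coherence
    connectivity matrices, weighted graph metrics (connection strength,
    characteristic path length, clustering coefficient), regional
    excitatory/inhibitory topographic-pattern classification, and the
    accompanying group statistics (Fisher exact tests on pattern
    prevalence, ANOVA on band power, Student t tests with Bonferroni
    correction, Spearman clinical correlations), orchestrated by a
    reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    igraph,
    optparse,
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
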