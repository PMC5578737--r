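Package: tim23ephys
Title: Single-Channel Electrophysiology of Tim23-Like Protein-Conducting
    Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for planar lipid bilayer recordings of
    Tim23-like mitochondrial protein-conducting channels: idealization of
    noisy current traces by penalized change-point detection, extraction of
    gating events and gating frequency, Gaussian-mixture decomposition of
    conductance-change amplitudes, open probability and Boltzmann
    voltage-dependence fits, Goldman-Hodgkin-Katz reversal-potential and
    permeability-ratio arithmetic, and presequence dose-response
    quantification. Includes a continuous-time Markov gating simulator that
    produces Tim23-like traces and current-voltage datasets with exact
    ground truth for validating every estimator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
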