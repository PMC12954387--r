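Package: metaseeg
Title: Static and Dynamic Functional Connectivity of Intracerebral EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis of static and dynamic functional brain networks in
    multichannel intracerebral (stereo-EEG) recordings. Implements
    leakage-orthogonalized amplitude envelope correlation, strength-normalized
    weighted graph metrics with bootstrap node downsampling and
    epileptogenic-zone aggregation, instantaneous amplitude correlation
    tensors, recurrence-plot meta-state detection by signed-modularity Louvain
    community detection, temporal activation sequences with dwell time and
    Lempel-Ziv complexity, amplitude-adjusted Fourier transform surrogate
    normalization, and a Friedman / Wilcoxon / false-discovery-rate
    three-condition comparison layer. A synthetic cohort generator with
    planted connectivity meta-states makes every stage testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    signal,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
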