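Package: dynflex
Title: Flexibility Analysis of Dynamic Functional Brain Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds sliding-window dynamic functional connectivity networks
    from region-of-interest fMRI time series, detects time-resolved community
    structure by optimizing multilayer modularity with ordinal inter-layer
    coupling (a generalized Louvain algorithm), and quantifies the temporal
    stability of each brain region as its flexibility (community switching
    rate). Provides covariate-adjusted group statistics (ANCOVA with
    dummy-coded site, Benjamini-Hochberg false-discovery-rate control,
    partial Pearson correlations with symptom scores), cohort quality-control
    filters, and a synthetic multi-site cohort generator with planted
    time-varying community structure for validation. Ships the Dosenbach
    160-ROI functional atlas with its six-subnetwork assignment.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    withr,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
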