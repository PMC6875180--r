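Package: netscale
Title: Multiscale Functional Brain-Network Construction, Feature Screening
    and Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how the node scale of a functional brain
    network parcellation affects graph-metric classification features.
    Subdivides a labelled atlas into parcellations of configurable node
    count by volume-proportional random-seed region growing, builds
    sparsity-thresholded binary networks from nodal time series, extracts
    area-under-curve integrated nodal graph metrics (degree, betweenness
    centrality, nodal efficiency), screens features with two-sample
    Kolmogorov-Smirnov tests under Benjamini-Hochberg false-discovery-rate
    control, classifies groups with a linear support vector machine under
    repeated stratified cross-validation, and evaluates feature
    effectiveness and redundancy with minimum-redundancy-maximum-relevance
    mutual-information scores.  Includes a synthetic resting-state fMRI
    cohort generator with planted group-level connectivity effects so the
    whole pipeline is testable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    e1071,
    RNifti,
    jsonlite
Suggests: testthat (>= 3.0.0), yaml, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
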