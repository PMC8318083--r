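Package: megstats
Title: Spatiotemporal Statistics for MEG Source Estimates: TFCE Permutation
    Inference, Searchlight Decoding and RDM-Based Directed Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for trial-level magnetoencephalography (MEG)
    source estimates arranged as trials x sources x time tensors. Provides
    two-stage mass-univariate regression (per-subject ordinary least squares
    followed by group-level one-sample tests) with threshold-free cluster
    enhancement (TFCE) and sign-flip max-statistic permutation inference on
    source x time grids; searchlight multivariate pattern classification of
    condition pairs with pseudo-trial averaging and leave-one-pair-out
    cross-validation; directed connectivity between functional regions of
    interest via lagged partial correlations of time-resolved representational
    dissimilarity matrices (RDMs); cosine-similarity association scoring of
    word pairs from distributional embeddings (including a PCA-reduced
    variant); and a seeded synthetic source-estimate generator with planted
    effects and lagged inter-region couplings for calibration and recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    igraph,
    e1071,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
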