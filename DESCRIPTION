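Package: guidescreen
Title: Guide Design, Compositional Screen Scoring, and Transfer-Learned
    Activity Prediction for Bacterial CRISPR sgRNA Pools
Version: 0.1.0
Authors@R:
    person("Screen", "Tools", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for pooled two-plasmid CRISPR sgRNA screens in bacteria:
    scanning sequences for NGG PAM target sites and designing exact-match and
    mismatch-tiled oligo pools; demultiplexing barcoded amplicon reads into
    guide count tables; scoring guide enrichment or depletion with a
    centred-log-ratio Dirichlet Monte-Carlo difference statistic and turning
    it into standardized activity scores; classifying growth-curve phenotypes;
    and predicting sgRNA activity from 28-nt target-site sequence with a
    dual-branch convolutional / convolutional-bidirectional-GRU regression
    network trained with a layer-freezing transfer-learning protocol from a
    large base dataset to small high-quality datasets. Includes synthetic data
    generators with the statistical structure these methods assume, a 5-fold
    cross-validation harness using Spearman rank correlation, and an
    input-window length sweep.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
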