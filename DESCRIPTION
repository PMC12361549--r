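Package: proteoTraj
Title: Multi-Organ Aging Proteomics: Moderated Tests, Trajectory
    Clustering and Network Hubs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for label-free quantitative proteomics
    of aging across multiple organs. Reads peptide-level quantification
    exports, applies record-level quality filters, normalizes and
    summarizes peptides to protein abundances by a robust two-way model,
    imputes missing values by iterative random-forest regression, and
    detects differentially expressed proteins with an empirical-Bayes
    moderated F-test alongside pairwise moderated t, classical F and
    linear age-trend tests. Downstream stages cluster z-scored age
    trajectories by fuzzy c-means with an estimated fuzzifier, quantify
    cross-organ overlap with hypergeometric tests, subtract
    blood-associated proteins, fit random-intercept mixed models for
    age-by-tissue divergence, rank protein network hubs by maximal clique
    centrality, and quantify internal-standard-triggered targeted-MS
    validation data. A synthetic-study generator with known ground truth
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    igraph,
    randomForest,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    limma,
    e1071,
    lme4,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
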