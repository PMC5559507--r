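Package: mspli
Title: Microstate-Segmented Phase-Lag-Index Connectivity Analysis for
    Resting-State EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative EEG pipeline linking behavioural scores to
    band-limited brain-network connectivity. Implements band-pass
    filtering and sliding-window Hilbert phase extraction, microstate
    segmentation by polarity-invariant (modified) k-means with
    Krzanowski-Lai selection of the number of classes, the
    microstate-segmented phase lag index (msPLI) with stitched-epoch
    averaging and region-of-interest aggregation, weighted graph
    measures with surrogate normalisation, and a confound-residualised
    Spearman correlation analysis with max-statistic permutation
    correction. A seeded synthetic-EEG generator with planted coupling
    and covariate effects provides ground truth for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    nortest,
    pROC,
    Rcpp,
    signal,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
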