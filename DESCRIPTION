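Package: tabready
Title: Machine-Learning Readiness Assessment for Labeled Tabular Datasets
Version: 0.1.0
Authors@R:
    person("tabready", "maintainers", email = "maintainers@tabready.dev",
           role = c("aut", "cre"))
Description: Quantifies how ready a labeled tabular dataset is for machine
    learning. Five quality metrics (mean absolute Pearson and Spearman
    correlation, missing-value fraction, MAD-rule outlier rows, and the
    k-nearest-neighbour class-overlap R value) are scored on randomly
    sampled sub-tables, dataset-specific metric weights are learned by
    regressing cross-validated classification accuracy and clustering
    silhouette on the metric scores with a random-forest regressor, and a
    random-restart search returns the highest-quality cleansed sub-table
    together with CSV/TXT reports. Includes a synthetic-data generator
    with planted quality defects for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    matrixStats,
    optparse,
    parallel,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
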