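Package: topcorr
Title: Large-Scale Correlation Network Construction via Projections and
    Metric Indexing
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constructs large correlation networks for high-dimensional
    biological data without materializing the full correlation matrix.
    Features are projected onto mean-centered unit vectors so that scalar
    products equal Pearson (or rank-based Spearman, or Phi) correlations
    and Euclidean distances are order-equivalent to correlations.  A joint
    ball-tree index over positive and negative projections supports
    approximate global top-k correlation search and exact threshold
    (radius) search; a paired differential-space representation extends
    both to top-k differential correlation discovery across two
    conditions.  Includes correlation p-values with Bonferroni and
    truncated Benjamini-Hochberg adjustment, correlation-preserving
    embedding coordinates, seeded synthetic data generators with planted
    ground truth, a single-cell functional-coordination recipe based on
    dual bootstrapping and Cliff's delta, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    Matrix,
    jsonlite,
    optparse,
    parallel,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
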