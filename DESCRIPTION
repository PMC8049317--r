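Package: protmiss
Title: Missingness Assessment, Imputation and Topology Comparison for
    Protein Quantitation Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to profile and reason about missing values in
    protein-level quantitation matrices from data-independent acquisition
    (DIA/SWATH) mass spectrometry. Provides missingness profiling per
    sample and per protein, five imputation engines (lowest-value,
    chained equations, iterative random forest, probabilistic PCA and
    multivariate-normal EM), threshold exploration with kernel-density
    comparison and two-sample Kolmogorov-Smirnov statistics between
    imputed and non-imputed data, a Mapper (topological data analysis)
    implementation with missingness-enriched nodes and community
    detection, a synthetic-data generator with controllable MCAR, MAR
    and left-censored MNAR mechanisms, and a non-interactive report
    runner with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    igraph,
    mclust,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
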