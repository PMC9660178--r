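Package: sasne
Title: Shape-Aware Stochastic Neighbor Embedding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Nonlinear dimensionality reduction for transcriptomics and other
    high-dimensional data that replaces the Euclidean input distances of t-SNE
    with biharmonic graph distances computed on a minimally-connected
    k-nearest-neighbor graph. Provides the graph construction with data-driven
    choice of k, spectral biharmonic and commute-time distance matrices, a
    t-SNE core operating on arbitrary precomputed distances with perplexity
    defaulting to 90 percent of the number of points, rank-based and
    silhouette-based embedding validation (mean absolute rank error, rank
    residual plots), four synthetic benchmark generators, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    igraph,
    jsonlite,
    data.table,
    tibble,
    dplyr,
    ggplot2,
    generics,
    rlang,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
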