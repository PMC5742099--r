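Package: connectofuse
Title: Fusing Multiple Edge Weightings of Structural Brain Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds structural brain networks from tractography-derived tract
    tables under nine edge-weighting strategies (FA, MD, RD, average tract
    length, Euclidean centroid distance, streamline density, tract volume, and
    the number and proportion of streamlines), fuses them into a single
    integrated weighted network using graph diffusion distances between
    Laplacian exponential kernels, and topologically filters the result by
    accumulating orthogonal minimal spanning trees up to the peak of global
    cost efficiency. Includes weighted network metrics, test-retest
    intraclass-correlation reliability, rank-sum comparisons, diffusion-distance
    k-nearest-neighbour fingerprinting with a quality-of-clustering index,
    classical multidimensional-scaling embeddings, node- and cluster-wise
    lesion weighting, and a synthetic multi-subject multi-scan cohort
    generator for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
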