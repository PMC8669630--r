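Package: xtalknet
Title: Typed Multilayer Gene Networks, Module Detection and Cell-Death
    Crosstalk Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds typed multilayer gene-interaction networks from
    tab-separated edge lists, aggregates relation layers into a single
    weighted matrix by convex combination, detects subnetwork modules by
    normalized-Laplacian spectral clustering with planted-partition
    likelihood refinement, scores modules against pathway gene sets with a
    hypergeometric network score and Fisher's exact test, quantifies
    crosstalk between cell-death-mode networks, and ships seeded
    generators of planted-module benchmark networks for calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    igraph,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
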