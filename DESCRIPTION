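Package: funsig
Title: Sign-Dependent Functional Modules from Correlation Matrices via
    Random Matrix Theory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects sign-dependent functional modules ("functional
    signatures") in multivariate activity recordings such as single-cell
    circadian bioluminescence traces.  A Wishart null model with a
    global-mode correction separates the eigenvalue spectrum of the
    Pearson correlation matrix into a random bulk, a global trend, and
    statistically significant structural components; a modularity
    optimization adapted to correlation matrices then partitions units
    into modules that are positively correlated internally and negatively
    correlated across.  Includes synthetic benchmark generators,
    threshold-network and signed-modularity baselines, consensus and
    hierarchical module detection, and signature statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    mclust,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
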