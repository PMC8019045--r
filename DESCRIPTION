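Package: clannet
Title: Temporal Social Network Analysis of Multi-Level Animal Societies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing temporal association patterns among the core
    units of a multi-level animal society from focal-follow scan samples.
    Computes simple association indices with dyad-count provenance, clusters
    units into clans by agglomerative clustering with cophenetic-correlation
    linkage selection, runs data-stream and node-level permutation tests for
    preferred association, builds sliding-window weighted networks with
    node and network metrics, cosine-similarity stability series and
    bootstrap intervals, regresses network metrics on standardized food
    availability and rainfall covariates with AR1-autocorrelated errors, and
    analyses the timing and dyadic after-effects of inter-unit male
    dispersal. Includes a synthetic multi-level-society generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ape,
    mclust,
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
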