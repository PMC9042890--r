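Package: twodea
Title: Two-Dimensional Enrichment Analysis on Signed Molecular Interaction Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Network-topology weighted enrichment analysis for curated
    molecular interaction maps. Computes signed shortest-path influence
    scores (transcriptional, catalytic and phenotype contexts) on a signed
    directed interaction graph, combines them with differential fold-change
    data to infer regulated downstream phenotypes (level, saturation and a
    bounded two-dimensional enrichment score) and upstream regulator targets
    (sensitivity, specificity and an adapted enrichment score), and assesses
    significance with a type-stratified permutation null, direction-specific
    half-Gaussian fits and Benjamini-Hochberg false discovery rate control.
    Includes a synthetic map and data generator so every stage is testable
    without external downloads, plus a small command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
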