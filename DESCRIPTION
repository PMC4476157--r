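Package: regnet
Title: Analysis of Curated Transcriptional Regulatory Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for working with literature-curated transcription factor
    (TF) to target regulatory maps: co-annotation quality scoring against a
    baseline network, reference-pathway recall, subnetwork topology with
    subsampling robustness, three-node motif census and enrichment against
    degree-preserving randomized nulls, Markov clustering of regulatory
    communities, binding-matrix information content and its relation to
    wiring, ancient/novel TF-family dating from phylogenetic presence
    profiles with wiring-preference tests, and Hill-kinetics ODE simulation
    of small regulatory circuits. Includes generators for synthetic networks,
    annotations, binding matrices and presence profiles with planted
    structure, so every stage can be exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    igraph,
    Matrix,
    deSolve,
    jsonlite,
    ggplot2,
    generics,
    yaml,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
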