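Package: admotif
Title: Monomeric and Dimeric Transcription Factor Motif Models with
    Adjacent Dinucleotide Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models transcription factor binding motifs as inhomogeneous
    first-order Markov chains (adjacent dinucleotide matrices, ADMs) and
    learns, from enriched read sets such as HT-SELEX windows, a probabilistic
    mixture of monomeric motifs and all their dimers (orientation, signed
    spacing, bridging components and their deviation from independence)
    with a seed-initialised, pruned ZOOPS expectation-maximisation
    algorithm. Includes a ZOOPS read simulator for validation, co-operative
    binding (COB) tables, an 85 percent submodel post-processor, and a k-mer
    occurrence/score R-squared evaluation of model fit.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    Biostrings
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
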