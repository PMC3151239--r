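Package: ogdscan
Title: Detection of Orthologous Gene Displacement by Exhaustive
    Phylogenetic Placement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects orthologous gene displacement (OGD), a stringent form of
    horizontal gene transfer in which an incoming ortholog replaces the
    resident copy of a universally single-copy gene. Every branch of a
    combined reference phylogeny is pruned and re-inserted at every possible
    position; candidate placements are scored by expected likelihood weights
    (RELL bootstrap of sitewise log-likelihoods under the JTT amino-acid
    model) and by the path-length distance from the original position.
    Includes the downstream factor analyses (GC content, habitat, genome
    size, evolutionary distance, interaction counts), transfer dating from
    donor/acceptor distances to their last common ancestor, rate-of-OGD
    linearity analysis, and a synthetic-data generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    Matrix,
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
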