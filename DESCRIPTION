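Package: chianet
Title: Chromatin Interaction Networks from Paired-Anchor Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds chromatin interaction networks from paired-anchor
    interaction data such as ChIA-PET output, either by merging overlapping
    interaction anchors or by snapping anchors onto open-chromatin peaks.
    Networks can be annotated with genomic intervals, variants, genes and
    promoters; analysed with node centralities (degree, betweenness,
    closeness, harmonic); mined for direct and indirect gene targets of
    annotated loci via exhaustive shortest-path discovery; and tested for
    enrichment of interactions between annotation classes with binomial and
    permutation nulls, plus Fisher's exact tests of target gene lists.
    Includes readers and writers for BEDPE, BED, gene tables and GML, a
    deterministic synthetic-fixture generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    igraph,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
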