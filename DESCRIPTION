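Package: paleoretain
Title: Paleopolyploidy Inference, Triplication-Retained Regions and
    Synteny-Based Gene-Loss Tracing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A comparative-genomics toolkit for inferring ancient
    whole-genome duplications and triplications from synonymous-divergence
    (Ks) distributions, chaining homologous gene pairs into collinear
    synteny blocks, calling triplication-retained regions (TRRs) against a
    reference genome with composition and enrichment statistics, tracing
    single-gene losses through syntenic context (including micro-inversion
    signatures at the lost locus), and classifying gene-family expansion
    mechanisms (tandem versus whole-genome-duplication derived). Includes a
    genome-evolution simulator that generates annotated genomes along a
    species tree with a known event log, so every inference stage can be
    validated against ground truth at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    ape,
    mclust,
    Biostrings,
    rtracklayer,
    IRanges,
    S4Vectors,
    GenomicRanges,
    GenomeInfoDb,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
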