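Package: chromsandbox
Title: Chromosome-Level 'Sandbox' Characterization from Genome, Expression and Pool-Seq Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the hallmarks of a genetically plastic "sandbox"
    chromosome: windowed GC content and gene density, pooled-read pairwise
    nucleotide diversity (pi) and Ts/Tv, cross-species gene conservation
    ratios from reciprocal protein hits, phylostratigraphic clade-specificity
    profiling from orthogroups, per-chromosome hypergeometric gene-set
    enrichment/depletion, pseudogene flagging from expression, tandem-array
    detection, and subfunctionalization analysis of tandem paralog islands
    (regulation-profile blocks, protein isoelectric points, heat-shock-element
    scanning, Nei-Gojobori dN/dS). Includes a seeded synthetic-genome
    generator emitting a complete FASTA/GFF3/VCF/TSV input bundle with a
    ground-truth manifest, so every stage is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
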