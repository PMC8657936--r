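Package: plastovar
Title: Comparative Plastome Variant Analysis and Haplotype Grouping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of near-identical chloroplast genomes:
    anchor-based pairwise whole-plastome alignment, classification and
    annotation of SNPs, indels (with homopolymer-run notation), tandem
    duplications and hairpin-mediated small inversions, multi-sample
    haplotype matrices with distance-based grouping and neighbor-joining
    trees, and in-silico PCR band-pattern haplotyping of marker loci.
    Includes a deterministic synthetic plastome generator with truth
    tables so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    S4Vectors,
    ape,
    rtracklayer,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
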