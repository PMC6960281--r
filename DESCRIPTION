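Package: crispriguides
Title: CRISPRi Guide RNA Design and Targetability Analysis for Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design toolkit for CRISPR interference (CRISPRi) in bacteria
    using type IIA Cas9 systems with degenerate protospacer-adjacent motifs
    (PAMs), such as Streptococcus thermophilus CRISPR3 (NGGNG) and
    Streptococcus pasteurianus (NNGTGA). Enumerates all PAM occurrences on
    both genome strands, extracts 20-nt protospacers, applies a 12-nt
    seed-region uniqueness filter against genome-wide off-target binding,
    selects nontemplate-strand guides inside a window around annotated
    transcription start sites, reports genome-wide gene and operon
    targetability, assembles full sgRNA construct sequences, and quantifies
    RNA-seq expression from paired-end alignments by fractional fragment
    coverage with pseudocounted RPKM and log2 fold changes. Includes a
    deterministic synthetic-fixture generator (GC-rich genomes with planted
    guide sites and synthetic alignments) so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    Rsamtools,
    GenomicAlignments,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    stringr,
    jsonlite,
    ggplot2,
    generics,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
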