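Package: mitescan
Title: Discovery and Characterization of Miniature Transposon-Like
    Insertions in Plant Genomes
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for discovering and characterizing
    miniature, non-autonomous transposon-like insertions such as the
    wheat element Mariam: seeded homology retrieval of element copies
    with e-value filtering and flank extraction, target-site-duplication
    (TSD), terminal-inverted-repeat (TIR) and SINE-hallmark
    classification, flank sequence logos, in-silico PCR scoring of
    insertional polymorphism across accession panels, Bray-Curtis
    clustering with SIMPROF similarity-profile permutation tests, and
    gene-impact analysis (splice-aware transcripts, ORF truncation,
    relative expression by the 2^-ddCt method).  A synthetic-genome
    module generates wheat-like test genomes, gene models, accession
    panels and qPCR CT tables with known ground truth so that every
    stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    rtracklayer,
    vegan,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
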