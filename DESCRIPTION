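Package: exonalign
Title: Exon-Centric Spliced Alignment of Annotated Protein Queries to Genomic DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Aligns a protein query with known exon boundaries to genomic DNA
    one exon at a time: translated local seeding with intron-size-aware
    chaining, a truncation filter, sensitive rescue of missing exons inside
    their synteny windows, splice-junction refinement that scores candidate
    GT/GC donors and AG acceptors under a reading-frame preservation
    constraint, start/stop codon refinement, and assembly into a gene model
    with per-exon peptides (split codons excluded), GFF3, FASTA and a
    machine-readable report. Includes a synthetic-fixture generator that
    plants genes with known exon/intron structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    dplyr,
    tibble,
    purrr,
    readr,
    rlang,
    withr,
    jsonlite,
    ggplot2,
    generics,
    methods,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
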