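Package: micseqr
Title: Discovery of Common Non-Reference Insertions from Pooled One-End-Anchored Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects common sequences missing from a reference genome
    assembly ("micSeqs") in shallow population-scale paired-end sequencing
    data. Read pairs in which exactly one mate aligns uniquely (one-end-
    anchored, OEA) are classified per sample; the unmapped orphan mates are
    pooled across the cohort, grouped by the anchor's chromosome, and
    assembled with a multi-k de Bruijn assembler under a stringent k-mer
    coverage cutoff so that only population-frequent sequences survive.
    Per-k assemblies are merged through a sequence-similarity graph,
    candidates are screened against the reference, low-complexity masking,
    anchor-position clustering, local reference sequence and contaminants,
    insertion breakpoints are estimated from stranded anchor clusters,
    per-sample carriers and population frequencies are called, and
    population stratification is tested with Fisher's exact test. A fully
    seeded diploid-population read simulator with an idealized aligner
    provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Rsamtools,
    data.table,
    igraph,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
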