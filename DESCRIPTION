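Package: gatascan
Title: Zinc-Finger Domain Typing and Cohort Analysis of Plant GATA
    Transcription Factors
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Detects class-IV zinc-finger GATA domains in plant protein
    sequences by cysteine-spacer grammar, classifies them into the
    spacer-defined types (IVa, IVb, IVc, IV4, IVe and the partial type
    IVp), quantifies alternative-splicing isoform structure per gene,
    builds per-position amino-acid frequency profiles stratified by taxon
    group, and emits cohort-level summary tables: per-species gene and
    isoform counts, domain-type counts and ratios by group, gene-count and
    sequence-length statistics, genus and order aggregations.  Includes a
    planted-motif synthetic proteome generator with a full ground-truth
    table so every pipeline stage can be benchmarked end to end without
    external downloads.
License: MIT + file LICENSE
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
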