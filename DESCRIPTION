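Package: rarecnv
Title: Rare Copy Number Variant Case-Control Analysis from SNP Array Calls
Version: 0.1.0
Authors@R: person("rarecnv", "maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quality control, cleaning and case-control analysis of rare copy
    number variants (CNVs) called from SNP array data. Reads PennCNV-style
    call files and quality summaries, applies per-sample signal-quality
    filters, removes calls in spurious genomic regions (HLA, centromeres,
    telomeres), merges artificially split adjacent calls, partitions variants
    into rare and common by union-intersection overlap counting in a
    reference control subset, computes size-binned case-control frequency
    comparisons (two-proportion tests, Woolf odds-ratio confidence
    intervals), global burden metrics with permutation p-values, and
    permutation-based gene-set enrichment via logistic regression. Includes a
    synthetic cohort generator so every stage is testable without external
    data, and a subcommand-style pipeline runner with cascade reporting.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
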