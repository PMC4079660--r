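Package: ervtrace
Title: Lineage-Specific Endogenous Retrovirus Insertion Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects species-specific endogenous retrovirus (ERV) insertions
    from RepeatMasker annotation plus outgroup genomes, classifies their
    structure (full-length provirus, solitary LTR, truncated), characterizes
    integration hallmarks (target-site duplications), identifies non-classical
    insertions with associated genomic deletions and breakpoint microhomology,
    screens internal reading frames for retrotransposition competence, dates
    elements by Kimura-2-parameter LTR divergence under two neutral-rate
    calibrations, and summarizes insertion polymorphism and chromosomal
    density. A synthetic-genome generator plants ground-truth insertion events
    (with a machine-readable truth ledger) so the whole pipeline is testable
    without reference genomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    tibble,
    tidyr,
    stats,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
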