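Package: rvregion
Title: Region-Based Rare-Variant Association Analysis for Noncoding
    Regulatory Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for collapsing (region-based) rare-variant association
    analysis of noncoding regulatory regions such as 3'UTRs, pre-miRNA
    genes and miRNA-target networks, alongside protein-coding controls.
    Provides site-level quality control (exact Hardy-Weinberg and
    differential-missingness filters), qualifying-variant rules for
    coding variants, a miRNA-recognition-element gain/loss caller based
    on seed-match scanning, covariate-adjusted burden/CMC, SKAT, SKAT-O
    and variable-threshold association statistics with permutation
    p-values and genomic-inflation diagnostics, ancestry principal
    components from LD-pruned common variants, carrier-level 2x2
    epidemiology with continuity corrections, onset-age permutation
    tests, and a deterministic synthetic cohort generator so the whole
    pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
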