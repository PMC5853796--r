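Package: hexameta
Title: Hexamer Association Meta-Analysis for Cis-Regulatory Element Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Discovers candidate cis-regulatory hexamers in promoters of
    responsive genes by meta-analysis over many differential-expression data
    sets. Scans TSS-anchored upstream windows for all canonical (reverse
    complement collapsed) hexamers, tests per-dataset association between
    hexamer presence and up/down regulation with one-sided Fisher exact
    tests, combines p-values across data sets with Fisher's method,
    assigns empirical significance by a promoter-shuffling permutation
    test, and tests positional hexamer enrichment within transcription
    factor binding peaks and chromatin-state segments. Includes a synthetic
    data generator with planted motifs so the whole pipeline is testable
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
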