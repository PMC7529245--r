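Package: k9balance
Title: Differential H3K9me2 and Transcript Analysis with TE-NLR Spatial
    Statistics
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for genome-wide chromatin/expression
    balance analysis of plant immune receptor (NLR) genes: per-feature
    differential testing of H3K9me2 ChIP-seq and RNA-seq count matrices
    between two genotypes (negative-binomial Wald test with
    median-of-ratios normalization and Benjamini-Hochberg correction),
    joint direction classification of chromatin and transcript changes,
    chi-square balance tests of up/down regulated gene categories,
    transposable-element/NLR spatial association with resampling nulls,
    chromosome-compartment TE superfamily enrichment with randomized
    Fisher tests, and detection of alternative proximal polyadenylation
    from strand-aware coverage tracks. Includes seeded synthetic-data
    generators with planted truth so every stage is testable end to end
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    rtracklayer,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
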