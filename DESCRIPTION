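Package: allelome
Title: Allelic Expression and Chromatin Classification for F1 Reciprocal Crosses
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies genes into allelic expression categories (biallelic,
    strain-biased, imprinted, not informative) from SNP-level allele-resolved
    read counts of reciprocal F1 hybrid crosses, using a binomial allelic
    score with an empirical false discovery rate set by mock comparisons that
    cancel true allelic signal. Builds on the classification to call X
    chromosome inactivation escapers under skewed or imprinted XCI, to test
    allele-specific histone-mark enrichment near transcription start sites and
    inside imprinted regions, to attribute strain bias to transcriptional or
    post-transcriptional causes via intron/exon contrasts, and to validate and
    catalogue imprinted gene candidates including cluster extents. Ships a
    seeded synthetic-data generator with a known truth table so every stage is
    testable without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
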