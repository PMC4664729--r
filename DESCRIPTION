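Package: crossbias
Title: Parent-Specific Gene Expression Analysis for Reciprocal Hybrid Crosses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of allele-specific read counts from reciprocal F1 hybrid
    families to disentangle parent-of-origin from allele(lineage)-of-origin
    expression effects. Provides beta-binomial likelihood-ratio tests of
    allelic imbalance with replicate-level overdispersion, a nine-way bias
    category system over the two reciprocal families, negative-binomial
    exact-test differential expression between families, chi-square
    goodness-of-fit enrichment of bias categories in QTL intervals and gene
    sets, detection of genomic clusters of biased genes, and a synthetic
    reciprocal-cross data generator with known truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR
Config/testthat/edition: 3
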