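Package: prc2induction
Title: Coordinate Induction of PRC2/H3K27me3-Marked Genes During Fungal
    Sexual Development
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for studying coordinate induction of
    Polycomb (PRC2/H3K27me3)-marked genes across an RNA-seq expression
    compendium, motivated by sexual development in Neurospora crassa.
    Derives the marked gene set from replicate ChIP-seq peak intervals
    (two-replicate intersection with an expressed-boundary-gene filter),
    computes a per-experiment induction score (mean TPM+1 of the set times
    the percentage of set genes with expression z-score above a
    threshold), classifies developmentally induced genes (DIGs) from
    differential-expression contrasts, quantifies set overlaps with
    hypergeometric enrichment, and implements tie-corrected
    Kruskal-Wallis, Dunn post hoc and Holm adjustment from first
    principles for fruiting-body morphometry. A synthetic-data module
    generates all inputs with planted ground truth so every stage has a
    parameter-recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
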