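Package: mirkd
Title: Whole-Blood Small RNA miR-ome Analysis for Kawasaki Disease
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A desk-scale re-implementation of a whole-blood small RNA
    sequencing analysis of acute versus convalescent Kawasaki disease:
    a synthetic read simulator with planted ground truth, 3' adapter
    trimming with length and Phred quality filters, hierarchical
    zero-mismatch annotation of reads to microRNA loci with isomiR and
    dominant-read summaries, a negative-binomial conditional exact test
    for paired-cohort differential expression with median-of-ratios
    normalization and Benjamini-Hochberg adjustment, miTG-score
    thresholded Fisher pathway enrichment of predicted targets, and the
    clinical statistics used for validation (RNU48-normalized qRT-PCR
    abundance, exact Wilcoxon signed-rank and Mann-Whitney tests,
    Spearman correlation, a Monte-Carlo power simulation for the paired
    design, and the RNase-protection vesicle fraction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    DESeq2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
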