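Package: casteChIP
Title: Caste-Differential Histone Mark and Expression Analysis with
    Synthetic Ground Truth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for comparing H3K4me1 ChIP-seq peak
    landscapes and gene expression between honey bee larval castes:
    replicate-consistent unique-peak and fold-change differential-peak
    classification, promoter/intron/exon peak annotation with chi-squared
    distribution tests, self-contained negative-binomial differential
    expression with Benjamini-Hochberg FDR and FPKM, peak-gene-expression
    integration (Spearman correlation, set overlap, hypergeometric
    over-representation, TSS metaprofiles), and 2^-ddCt qPCR relative
    quantification. A synthetic-data module generates genomes, peak sets,
    count matrices and Ct tables with planted ground truth so every stage
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    optparse
Config/testthat/edition: 3
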