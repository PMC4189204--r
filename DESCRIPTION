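Package: clonemethyl
Title: Differential DNA Methylation and Gene Expression Analysis for
    Two-Group MeDIP-seq and RNA-seq Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reusable pipeline for comparing genome-wide DNA methylation
    (MeDIP-seq) and gene expression (RNA-seq) between two unreplicated
    groups, as in cloned-animal phenotype studies. Provides window-based
    read-depth normalisation, sliding-window CpG-island detection,
    global-lambda Poisson peak calling, chi-square + FDR + fold-change
    differential methylation with gene-element annotation, two-proportion
    u-tests for repetitive-element read fractions, an Audic-Claverie exact
    test for digital gene expression between two libraries, RPKM
    expression tiers, metagene methylation profiles stratified by
    expression level, qPCR delta-delta-Ct and bisulfite-clone chi-square
    validation arithmetic, and a synthetic-data generator with planted
    truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    tools,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    Rsamtools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
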