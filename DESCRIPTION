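Package: genebody
Title: Gene-Body DNA Methylation, Expression and Chromatin Meta-Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genome-wide meta-analysis of gene-body DNA methylation
    against gene expression and chromatin state. Merges transcript models into
    distinct gene loci, aggregates per-CpG percent methylation over arbitrary
    region sets and metagene windows anchored at the TSS and TTS, quantifies
    promoter activity from CAGE tag clusters and tag densities for Pol2
    ChIP-seq and DNase I hypersensitivity assays, and relates the resulting
    per-gene measures through quantile binning and Pearson regression on bin
    means. Includes a synthetic-data generator implementing an
    accessibility-interference model of gene-body methylation (chromatin
    opening at low expression, polymerase interference with methyltransferase
    processivity at high expression) so that every pipeline stage can be
    exercised and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
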