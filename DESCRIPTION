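Package: lightomics
Title: Integrative Transcriptome, Small RNA and DNA Methylome Analysis of
    Light-Responsive Gene Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrative pipeline for studying far-red-light-induced
    regulatory reprogramming in the parasitic plant Cuscuta campestris.
    Provides negative-binomial differential expression with fold-change and
    FDR gates, TPM normalization, fuzzy c-means soft clustering of
    time-course profiles, Fisher-Z-thresholded gene co-expression networks
    around phytochrome hubs, hypergeometric functional-bin enrichment,
    small-RNA size-class profiling, differentially methylated region (DMR)
    calling from per-cytosine bisulfite reports, and an RNA-directed DNA
    methylation (RdDM) consistency classification joining methylation,
    small-RNA accumulation and expression. A synthetic-data module with
    planted ground truth makes every stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    igraph,
    jsonlite,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    e1071,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
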