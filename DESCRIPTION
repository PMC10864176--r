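Package: egrnet
Title: Enhancer-Gene Regulatory Network Inference from Paired Single-Nucleus Multiome Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for regulatory-genomics analysis of
    paired single-nucleus RNA and ATAC data sharing a low-dimensional latent
    space. Implements cross-modality nucleus pairing and expression
    imputation, windowed peak-to-gene link calling by Pearson correlation
    with false-discovery-rate filtering, recovery-AUC/NES motif enrichment
    and transcription-factor mining, assembly and export of tripartite
    TF to cis-element to target-gene networks, supervised pseudotime on
    two-dimensional embeddings, consensus differential expression and
    accessibility testing, internal cluster-quality indices, and a fully
    seeded synthetic paired-multiome generator with planted regulatory
    programs and trajectory ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    igraph,
    mclust,
    yaml,
    withr,
    generics,
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    cluster,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
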