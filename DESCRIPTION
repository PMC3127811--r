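Package: mitonet
Title: Network Analysis of Mitochondrial Proteome Remodeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for analysing quantitative mitochondrial proteomics
    under mitochondrial DNA depletion. Classifies protein abundance ratios
    into regulation classes, evaluates protein reliability against reference
    catalogs and interaction evidence, builds a functional association
    network and its intra/inter-regulatory link statistics, detects
    functional modules by average-linkage clustering on confidence-score
    similarity with hypergeometric enrichment labelling, and compares
    proteome and transcriptome ratios via k-means concordance grouping.
    Includes a synthetic-world generator with planted module, regulation,
    and concordance structure so that every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    igraph,
    limma,
    stats,
    utils,
    generics,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
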