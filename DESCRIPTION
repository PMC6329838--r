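Package: apexdomains
Title: Domain-Resolved Translatome Analysis of the Shoot Apex
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for domain-resolved TRAP-seq (translating
    ribosome affinity purification) expression profiles, as used to dissect
    the Arabidopsis shoot apex into promoter-defined cell domains. Implements
    RPKM normalization and expressed-gene calling, pairwise exact
    negative-binomial differential expression with Benjamini-Hochberg
    correction, three domain-specificity callers (pairwise union screen,
    z-score, compartment-specificity score), a log2 odds-ratio plus
    hypergeometric category-enrichment engine, weighted co-expression network
    module detection with eigengene merging and module-domain association,
    isoform-level domain-specific alternative-splicing calls, novel-lncRNA
    classification from assembled transcripts, and a synthetic-data generator
    with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
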