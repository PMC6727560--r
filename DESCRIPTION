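Package: cardiosex
Title: Sex-Stratified Analysis of Cardiac Development Transcriptomes
Version: 0.1.0
Authors@R: person("cardiosex", "authors", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for dissecting sex-biased gene expression across mouse
    cardiac development, from embryonic stem (ES) cells and derived cardiac
    precursors through embryonic, neonatal and adult hearts. Implements
    single-cell sex inference from the Xist/Eif2s3y expression ratio,
    per-stage differential-bias testing with false discovery rate control,
    weighted gene co-expression network construction (soft-threshold
    selection, topological overlap, module eigengenes and module-trait
    correlation), cross-stage bias-trajectory classification into groups
    I-V, protein-interaction community and centrality analysis, promoter
    motif scanning with exact p-value thresholds, and chromatin coverage
    metaprofiles. Ships synthetic-data generators with ground-truth
    sidecars so every stage of the pipeline is testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    tools,
    igraph,
    jsonlite,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
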