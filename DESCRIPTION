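Package: dupdiverge
Title: Transcriptional and Cis-Regulatory Divergence of Duplicated Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for studying how duplicated genes diverge in
    expression and in the sequence of their accessible chromatin regions
    (ACRs). Classifies duplicate pairs into expression-pattern categories
    from pseudobulk single-cell counts, scores sequence conservation of
    ACRs between paralogs with a short-match-tuned local aligner, derives
    conservation-count states across four-gene whole-genome-duplication
    sets, quantifies accessibility-profile overlap across tissues, and
    infers evolutionary trajectories of cell-type-specific expression by
    clustering binary specificity profiles. Ships a synthetic-data
    generator with planted ground truth so every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    edgeR,
    cluster,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
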