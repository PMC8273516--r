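Package: LeydigMarkers
Title: Marker-Gene Specificity Calling for Fetal and Adult Leydig Cells
    from Bulk and Single-Cell RNA-Seq
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies cell-population-specific marker genes by intersecting
    bulk RNA-seq negative-binomial differential expression with single-cell
    Wilcoxon rank-sum marker statistics under detection-fraction filters,
    applied to the fetal versus adult Leydig cell contrast in mouse testis.
    Also provides a droplet barcode-rank cell-calling threshold (knee,
    inflection, and density local minimum), RPKM quantification with biotype
    accounting, summarization of rMATS-format differential-splicing tables,
    hypergeometric over-representation and pre-ranked GSEA statistics, and a
    synthetic-data generator with planted ground truth that makes every stage
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    BiocGenerics,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    fgsea,
    mclust,
    withr,
    knitr,
    rmarkdown
biocViews: Transcriptomics, SingleCell, DifferentialExpression,
    GeneExpression, AlternativeSplicing, GeneSetEnrichment
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
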