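#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   rowData<- colData colData<-
#' @importFrom S4Vectors metadata metadata<- DataFrame
#' @importFrom BiocGenerics counts
NULL

#' CountMatrix: a genes-by-columns count container
#'
#' An S4 class extending [SummarizedExperiment::SummarizedExperiment] that
#' stores a non-negative integer count matrix (dense for bulk samples, sparse
#' `dgCMatrix` for single-cell UMI data) together with a `kind` flag
#' (`"bulk"` or `"single_cell"`) in its metadata. Gene annotation (id,
#' symbol, exonic length, biotype) lives in `rowData`; cell labels (cluster,
#' stage) in `colData` for single-cell matrices.
#'
#' @export
setClass("CountMatrix", contains = "SummarizedExperiment")

setValidity("CountMatrix", function(object) {
    msg <- character()
    if (!"counts" %in% names(assays(object)))
        msg <- c(msg, "assay 'counts' is missing")
    else {
        m <- assay(object, "counts")
        mn <- if (inherits(m, "sparseMatrix")) {
            if (length(m@x)) min(m@x) else 0
        } else if (length(m)) min(m) else 0
        if (is.na(mn) || mn < 0)
            msg <- c(msg, "counts contain negative or missing entries")
    }
    kind <- metadata(object)$kind
    if (is.null(kind) || !kind %in% c("bulk", "single_cell"))
        msg <- c(msg, "metadata kind must be 'bulk' or 'single_cell'")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene ids (rownames) must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "column ids (colnames) must be present and unique")
    if (length(msg)) msg else TRUE
})

#' Construct a CountMatrix
#'
#' @param counts numeric matrix or `dgCMatrix`, genes in rows, samples or
#'   cells in columns, with unique dimnames. Entries must be non-negative.
#' @param kind `"bulk"` or `"single_cell"`.
#' @param annotation optional gene annotation `data.frame` with at least a
#'   `gene_id` column covering every row of `counts`; stored in `rowData`.
#' @return A [CountMatrix-class] object.
#' @examples
#' m <- matrix(0:5, nrow = 3, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' cm <- CountMatrix(m, "bulk")
#' @export
CountMatrix <- function(counts, kind = c("bulk", "single_cell"),
                        annotation = NULL) {
    kind <- match.arg(kind)
    se <- SummarizedExperiment(assays = list(counts = counts))
    metadata(se)$kind <- kind
    obj <- new("CountMatrix", se)
    if (!is.null(annotation)) {
        validateGeneAnnotation(annotation)
        missing <- setdiff(rownames(counts), annotation$gene_id)
        if (length(missing))
            stop("genes absent from annotation: ",
                 paste(utils::head(missing, 10), collapse = ", "),
                 if (length(missing) > 10) sprintf(" (and %d more)",
                                                   length(missing) - 10))
        rowData(obj) <- DataFrame(
            annotation[match(rownames(counts), annotation$gene_id), ,
                       drop = FALSE], row.names = rownames(counts))
    }
    validObject(obj)
    obj
}

#' @describeIn CountMatrix counts accessor (the `counts` assay).
#' @param object a `CountMatrix`.
#' @export
setMethod("counts", "CountMatrix", function(object) assay(object, "counts"))

#' Kind of a CountMatrix
#'
#' @param x a `CountMatrix`.
#' @return `"bulk"` or `"single_cell"`.
#' @export
matrixKind <- function(x) {
    stopifnot(is(x, "CountMatrix"))
    metadata(x)$kind
}

#' Gene annotation of a CountMatrix
#'
#' @param x a `CountMatrix`.
#' @return `rowData` as a base `data.frame` (empty if no annotation attached).
#' @export
geneAnnotation <- function(x) {
    stopifnot(is(x, "CountMatrix"))
    as.data.frame(rowData(x))
}

#' Cell labels of a single-cell CountMatrix
#'
#' @param x a `CountMatrix` of kind `"single_cell"` whose `colData` carries
#'   `cluster` and `stage` columns.
#' @return data.frame with `cell_id`, `cluster`, `stage`.
#' @export
cellLabels <- function(x) {
    stopifnot(is(x, "CountMatrix"), matrixKind(x) == "single_cell")
    cd <- as.data.frame(colData(x))
    if (!all(c("cluster", "stage") %in% names(cd)))
        stop("colData lacks cluster/stage labels")
    data.frame(cell_id = colnames(x), cluster = as.character(cd$cluster),
               stage = as.character(cd$stage), stringsAsFactors = FALSE)
}

setMethod("show", "CountMatrix", function(object) {
    cat("CountMatrix (", metadata(object)$kind, "): ",
        nrow(object), " genes x ", ncol(object), " ",
        if (metadata(object)$kind == "bulk") "samples" else "cells",
        "\n", sep = "")
    if (ncol(rowData(object)))
        cat("rowData:", paste(colnames(rowData(object)), collapse = ", "),
            "\n")
    if (ncol(colData(object)))
        cat("colData:", paste(colnames(colData(object)), collapse = ", "),
            "\n")
    invisible(NULL)
})

# Validate a gene annotation table: unique ids, positive integer lengths,
# non-empty biotypes.
validateGeneAnnotation <- function(annotation) {
    req <- c("gene_id", "gene_symbol", "length_bp", "biotype")
    miss <- setdiff(req, names(annotation))
    if (length(miss))
        stop("annotation lacks column(s): ", paste(miss, collapse = ", "))
    if (anyDuplicated(annotation$gene_id))
        stop("duplicate gene_id in annotation: ",
             paste(unique(annotation$gene_id[duplicated(annotation$gene_id)])[1:min(5, sum(duplicated(annotation$gene_id)))],
                   collapse = ", "))
    if (any(!is.finite(annotation$length_bp)) ||
        any(annotation$length_bp < 1) ||
        any(annotation$length_bp != round(annotation$length_bp)))
        stop("annotation length_bp must be positive integers")
    if (any(is.na(annotation$biotype)) || any(!nzchar(annotation$biotype)))
        stop("annotation biotype must be non-empty")
    invisible(TRUE)
}
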