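#' @importFrom Matrix readMM writeMM colSums rowSums t Diagonal sparseMatrix
NULL

#' Read a gene annotation table ("GTF-lite")
#'
#' A 4-column tab-delimited table with header
#' `gene_id  gene_symbol  length_bp  biotype`, where `length_bp` is the
#' union-exon length in base pairs and `biotype` the transcript-type class
#' (e.g. `protein_coding`, `lncRNA`). Full GTF parsing is deliberately out of
#' scope; only these four fields anchor RPKM and biotype accounting.
#'
#' @param path file path.
#' @return data.frame with the four validated columns.
#' @export
readGeneAnnotation <- function(path) {
    ann <- readTsv(path)
    validateGeneAnnotation(ann)
    ann
}

#' Write a gene annotation table
#' @param annotation annotation data.frame.
#' @param path output path.
#' @export
writeGeneAnnotation <- function(annotation, path) {
    validateGeneAnnotation(annotation)
    writeTsv(annotation, path)
}

#' Read a bulk count table with its gene annotation
#'
#' The count table is a TSV whose header row names the samples and whose
#' first column holds gene ids; all cells must be non-negative integers.
#' Every gene id must be covered by the annotation; genes absent from it
#' abort with an error listing them.
#'
#' @param path count TSV path.
#' @param annotation_path annotation TSV path (see [readGeneAnnotation]).
#' @return list with `counts` (a bulk [CountMatrix-class]) and `annotation`.
#' @export
readBulkCounts <- function(path, annotation_path) {
    ann <- readGeneAnnotation(annotation_path)
    raw <- readTsv(path, colClasses = "character")
    if (ncol(raw) < 2) stop("count table needs a gene column and >=1 sample")
    ids <- raw[[1]]
    if (anyDuplicated(ids))
        stop("duplicate gene id in count table: ",
             ids[duplicated(ids)][1])
    m <- matrix(NA_real_, nrow(raw), ncol(raw) - 1,
                dimnames = list(ids, colnames(raw)[-1]))
    for (j in seq_len(ncol(m))) {
        v <- suppressWarnings(as.numeric(raw[[j + 1]]))
        bad <- which(is.na(v) & !is.na(raw[[j + 1]]))
        if (length(bad))
            stop(sprintf("malformed numeric cell at row %d, column '%s': '%s'",
                         bad[1], colnames(m)[j], raw[bad[1], j + 1]))
        m[, j] <- v
    }
    neg <- which(m < 0, arr.ind = TRUE)
    if (nrow(neg))
        stop(sprintf("negative count at gene '%s', sample '%s'",
                     rownames(m)[neg[1, 1]], colnames(m)[neg[1, 2]]))
    if (any(m != round(m)))
        stop("count table contains non-integer values")
    if (max(m) <= .Machine$integer.max) storage.mode(m) <- "integer"
    list(counts = CountMatrix(m, "bulk", annotation = ann),
         annotation = ann)
}

#' Write a bulk count table
#' @param x a bulk `CountMatrix`.
#' @param path output TSV path.
#' @export
writeBulkCounts <- function(x, path) {
    stopifnot(is(x, "CountMatrix"), matrixKind(x) == "bulk")
    m <- as.matrix(counts(x))
    df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
    writeTsv(df, path)
}

#' Read a sparse UMI matrix (MatrixMarket + sidecars)
#'
#' Reads the CellRanger on-disk convention: a MatrixMarket coordinate file
#' with features in rows and cells in columns, plus line-delimited barcode
#' and feature lists. The feature file may carry one to three tab-separated
#' columns (id, symbol, type); the first is used as the gene id.
#'
#' @param mtx_path MatrixMarket file.
#' @param barcodes_path one barcode per line.
#' @param features_path one feature per line.
#' @return a single-cell [CountMatrix-class] (genes x cells, `dgCMatrix`).
#' @export
readUmiMtx <- function(mtx_path, barcodes_path, features_path) {
    m <- as(readMM(mtx_path), "CsparseMatrix")
    barcodes <- readLines(barcodes_path)
    feats <- readLines(features_path)
    if (!length(barcodes)) stop("barcode file is empty")
    if (!length(feats)) stop("feature file is empty")
    features <- vapply(strsplit(feats, "\t"), `[`, "", 1)
    if (nrow(m) != length(features))
        stop(sprintf("MTX has %d rows but feature file lists %d features",
                     nrow(m), length(features)))
    if (ncol(m) != length(barcodes))
        stop(sprintf("MTX has %d columns but barcode file lists %d barcodes",
                     ncol(m), length(barcodes)))
    dimnames(m) <- list(features, barcodes)
    CountMatrix(m, "single_cell")
}

#' Write a sparse UMI matrix with its sidecars
#' @param x a single-cell `CountMatrix`.
#' @param mtx_path,barcodes_path,features_path output paths.
#' @export
writeUmiMtx <- function(x, mtx_path, barcodes_path, features_path) {
    stopifnot(is(x, "CountMatrix"), matrixKind(x) == "single_cell")
    m <- counts(x)
    writeMM(as(m, "generalMatrix"), mtx_path)
    writeLines(colnames(m), barcodes_path)
    writeLines(rownames(m), features_path)
    invisible(mtx_path)
}

.rmats_event_types <- c("SE", "RI", "A5SS", "A3SS", "MXE")

#' Read rMATS-style differential splicing tables from a directory
#'
#' One tab-delimited file per event type, named like `RI.MATS.JC.txt`; the
#' leading token identifies the event type. Mandatory columns: `GeneID`,
#' `geneSymbol`, `FDR`, `IncLevelDifference`. Column names are standardized
#' to `gene_id`, `gene_symbol`, `fdr`, `inc_level_difference`, and an
#' `event_type` column is added.
#'
#' @param dir directory path.
#' @param dialect junction-count dialect token in the file names, default
#'   `"JC"`; `"JCEC"` accepted.
#' @return named list of splicing event data.frames, one per file found.
#' @export
readRmatsTables <- function(dir, dialect = c("JC", "JCEC")) {
    dialect <- match.arg(dialect)
    files <- list.files(dir, pattern = paste0("\\.MATS\\.", dialect,
                                              "\\.txt$"),
                        full.names = TRUE)
    if (!length(files)) stop("no *.MATS.", dialect, ".txt files in ", dir)
    out <- list()
    for (f in files) {
        token <- sub("\\..*$", "", basename(f))
        if (!token %in% .rmats_event_types)
            stop("unknown event-type token '", token, "' in file ",
                 basename(f))
        tab <- readTsv(f)
        req <- c("GeneID", "geneSymbol", "FDR", "IncLevelDifference")
        miss <- setdiff(req, names(tab))
        if (length(miss))
            stop("file ", basename(f), " lacks mandatory column(s): ",
                 paste(miss, collapse = ", "))
        ev <- data.frame(event_type = token,
                         gene_id = as.character(tab$GeneID),
                         gene_symbol = as.character(tab$geneSymbol),
                         fdr = as.numeric(tab$FDR),
                         inc_level_difference =
                             as.numeric(tab$IncLevelDifference),
                         stringsAsFactors = FALSE)
        validateSplicingEvents(ev)
        out[[token]] <- ev
    }
    out
}

#' Write a splicing event table in rMATS column dialect
#' @param events standardized event data.frame (one event type).
#' @param path output path; conventionally `<TYPE>.MATS.JC.txt`.
#' @export
writeRmatsTable <- function(events, path) {
    validateSplicingEvents(events)
    out <- data.frame(GeneID = events$gene_id,
                      geneSymbol = events$gene_symbol,
                      FDR = events$fdr,
                      IncLevelDifference = events$inc_level_difference)
    writeTsv(out, path)
}

validateSplicingEvents <- function(ev) {
    if (!all(ev$event_type %in% .rmats_event_types))
        stop("event_type outside {",
             paste(.rmats_event_types, collapse = ","), "}")
    bad <- which(is.na(ev$fdr) | ev$fdr < 0 | ev$fdr > 1)
    if (length(bad))
        stop(sprintf("FDR out of [0,1] at row %d (value %s)", bad[1],
                     format(ev$fdr[bad[1]])))
    bad <- which(is.na(ev$inc_level_difference) |
                 abs(ev$inc_level_difference) > 1)
    if (length(bad))
        stop(sprintf("IncLevelDifference out of [-1,1] at row %d", bad[1]))
    invisible(TRUE)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: per line a set name, a description, then the member gene
#' symbols, all tab-delimited. Duplicate members within a line are collapsed
#' with a warning.
#'
#' @param path GMT file path.
#' @return named list of character member vectors, with a `descriptions`
#'   attribute (named character).
#' @export
readGmt <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    short <- which(lengths(parts) < 3)
    if (length(short))
        stop(sprintf("GMT line %d has fewer than 3 fields", short[1]))
    sets <- lapply(parts, function(p) p[-(1:2)])
    names(sets) <- vapply(parts, `[`, "", 1)
    desc <- vapply(parts, `[`, "", 2)
    names(desc) <- names(sets)
    for (i in seq_along(sets)) {
        if (anyDuplicated(sets[[i]])) {
            warning("duplicate members collapsed in set '",
                    names(sets)[i], "'")
            sets[[i]] <- unique(sets[[i]])
        }
    }
    attr(sets, "descriptions") <- desc
    sets
}

#' Write a GMT gene-set file
#' @param sets named list of member vectors, optionally with a
#'   `descriptions` attribute.
#' @param path output path.
#' @export
writeGmt <- function(sets, path) {
    desc <- attr(sets, "descriptions")
    if (is.null(desc)) desc <- setNames(rep("", length(sets)), names(sets))
    lines <- vapply(seq_along(sets), function(i)
        paste(c(names(sets)[i], desc[[names(sets)[i]]], sets[[i]]),
              collapse = "\t"), "")
    writeLines(lines, path)
    invisible(path)
}
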