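#' @importFrom stats cor var
NULL

#' RPKM quantification
#'
#' `rpkm(g, s) = 1e9 * count(g, s) / (length_bp(g) * total_counts(s))`,
#' i.e. reads per kilobase of union-exon length per million mapped reads,
#' using each sample's column total as the million-mapped denominator.
#'
#' @param counts a bulk [CountMatrix-class] or plain count matrix.
#' @param annotation gene annotation covering every matrix gene.
#' @return numeric matrix of RPKM values (genes x samples).
#' @export
computeRpkm <- function(counts, annotation) {
    m <- if (is(counts, "CountMatrix")) as.matrix(counts(counts)) else counts
    validateGeneAnnotation(annotation)
    idx <- match(rownames(m), annotation$gene_id)
    if (anyNA(idx))
        stop("genes absent from annotation: ",
             paste(utils::head(rownames(m)[is.na(idx)], 5), collapse = ", "))
    len <- annotation$length_bp[idx]
    tot <- colSums(m)
    zero <- which(tot == 0)
    if (length(zero))
        stop("sample with zero total counts: ", colnames(m)[zero[1]])
    1e9 * sweep(m / len, 2, tot, `/`)
}

#' Expressed-gene filter
#'
#' Genes whose mean RPKM across the given sample group reaches
#' `min_rpkm` (inclusive: the boundary value 1 counts as expressed).
#'
#' @param rpkm RPKM matrix.
#' @param samples sample names or indices defining the group (default: all).
#' @param min_rpkm threshold, default 1.
#' @return character vector of gene ids.
#' @export
expressedGenes <- function(rpkm, samples = colnames(rpkm), min_rpkm = 1) {
    if (!length(samples)) stop("sample group is empty")
    rownames(rpkm)[rowMeans(rpkm[, samples, drop = FALSE]) >= min_rpkm]
}

#' Biotype proportions among expressed genes
#'
#' Among genes with mean RPKM strictly above zero, the percentage of each
#' annotation biotype. Percentages sum to 100; with no expressed genes an
#' empty vector is returned.
#'
#' @param rpkm RPKM matrix.
#' @param annotation gene annotation.
#' @return named numeric vector of percentages.
#' @export
biotypeProportions <- function(rpkm, annotation) {
    validateGeneAnnotation(annotation)
    expressed <- rownames(rpkm)[rowMeans(rpkm) > 0]
    if (!length(expressed)) return(setNames(numeric(0), character(0)))
    bt <- annotation$biotype[match(expressed, annotation$gene_id)]
    if (anyNA(bt)) stop("expressed gene missing from annotation")
    tab <- table(bt)
    100 * as.numeric(tab) / sum(tab) -> p
    setNames(p, names(tab))
}

#' Transcriptome share of a gene subset
#'
#' `100 * sum(mean RPKM over the subset) / sum(mean RPKM over all genes)`
#' for the chosen sample group.
#'
#' @param rpkm RPKM matrix.
#' @param genes gene ids of the subset (must be rows of `rpkm`).
#' @param samples sample group (default all).
#' @return percentage (scalar).
#' @export
transcriptomeShare <- function(rpkm, genes, samples = colnames(rpkm)) {
    if (!all(genes %in% rownames(rpkm)))
        stop("subset contains genes absent from the matrix")
    mu <- rowMeans(rpkm[, samples, drop = FALSE])
    denom <- sum(mu)
    if (denom == 0) stop("zero total RPKM in the chosen samples")
    100 * sum(mu[genes]) / denom
}

#' Pairwise Spearman correlations between samples
#'
#' Symmetric matrix with unit diagonal; Spearman uses average ranks for
#' ties. A constant sample vector has no defined coefficient and is
#' reported as `NA`.
#'
#' @param rpkm RPKM (or any expression) matrix with >= 2 columns.
#' @return samples x samples correlation matrix.
#' @export
sampleCorrelations <- function(rpkm) {
    if (ncol(rpkm) < 2) stop("need at least 2 samples")
    rho <- suppressWarnings(cor(rpkm, method = "spearman"))
    const <- apply(rpkm, 2, function(v) length(unique(v)) == 1)
    rho[const, ] <- NA_real_
    rho[, const] <- NA_real_
    diag(rho) <- 1
    rho
}
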