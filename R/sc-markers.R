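#' @importFrom stats wilcox.test
NULL

#' Library-size normalization of single-cell UMI counts
#'
#' `x(g, c) = ln(1 + scale * count(g, c) / total(c))`, the log1p
#' counts-per-`scale` transform. Sparsity is preserved (a zero count maps
#' to zero).
#'
#' @param umi single-cell [CountMatrix-class] or matrix (genes x cells).
#' @param scale library-size target, default 10,000.
#' @return normalized matrix (same storage class as the input counts).
#' @export
normalizeCells <- function(umi, scale = 10000) {
    m <- if (is(umi, "CountMatrix")) counts(umi) else umi
    tot <- Matrix::colSums(m)
    zero <- which(tot == 0)
    if (length(zero))
        stop("cell with zero total counts: ", colnames(m)[zero[1]])
    if (inherits(m, "CsparseMatrix")) {
        per_entry <- rep.int(tot, diff(m@p))
        m@x <- log1p(scale * m@x / per_entry)
        m
    } else {
        log1p(scale * sweep(as.matrix(m), 2, tot, `/`))
    }
}

#' Wilcoxon rank-sum marker statistics for one contrast
#'
#' Computes, per gene, the detection fractions `pct_1`/`pct_2` (fraction of
#' cells with a nonzero count inside / outside the focal group) and the
#' average log fold change
#' `avg_logfc = ln(mean_in(e^x - 1) + 1) - ln(mean_out(e^x - 1) + 1)`
#' (natural log of de-normalized group means). A gene is tested only when
#' `max(pct_1, pct_2) >= min_pct` and (with `positive_only`)
#' `avg_logfc >= logfc_prefilter`; tested genes get a two-sided
#' Mann-Whitney p-value (normal approximation with tie and continuity
#' correction), adjusted over the full gene universe (Bonferroni by
#' default, the cited single-cell toolchain's convention; BH by flag).
#' Untested genes carry `p_value = p_adjusted = 1` and never pass.
#'
#' A gene passes the marker criteria when `p_adjusted < padj_max`,
#' `avg_logfc > logfc_min`, `pct_1 > pct_in_min` and `pct_2 < pct_out_max`
#' (all strict).
#'
#' @param norm normalized expression matrix from [normalizeCells()].
#' @param cells_in,cells_out disjoint cell-id sets, each of size >= 3.
#' @param min_pct detection prefilter, default 0.25.
#' @param logfc_prefilter average-logFC prefilter, default 0.25.
#' @param positive_only only test genes up in the focal group (default).
#' @param adjust_method `"bonferroni"` (default) or `"BH"`, applied over the
#'   full gene universe.
#' @param padj_max,logfc_min,pct_in_min,pct_out_max pass criteria, defaults
#'   0.01 / 0.5 / 0.5 / 0.25.
#' @return data.frame (`MarkerStat`): `gene_id`, `p_value`, `avg_logfc`,
#'   `pct_1`, `pct_2`, `p_adjusted`, `tested`, `passes_marker_criteria`.
#' @export
wilcoxonMarkerTest <- function(norm, cells_in, cells_out, min_pct = 0.25,
                               logfc_prefilter = 0.25, positive_only = TRUE,
                               adjust_method = c("bonferroni", "BH"),
                               padj_max = 0.01, logfc_min = 0.5,
                               pct_in_min = 0.5, pct_out_max = 0.25) {
    adjust_method <- match.arg(adjust_method)
    if (length(intersect(cells_in, cells_out)))
        stop("cells_in and cells_out overlap")
    if (length(cells_in) < 3 || length(cells_out) < 3)
        stop("both cell sets need at least 3 cells")
    mi <- norm[, cells_in, drop = FALSE]
    mo <- norm[, cells_out, drop = FALSE]
    pct1 <- as.numeric(Matrix::rowSums(mi > 0)) / length(cells_in)
    pct2 <- as.numeric(Matrix::rowSums(mo > 0)) / length(cells_out)
    mean_in <- as.numeric(Matrix::rowSums(expm1(mi))) / length(cells_in)
    mean_out <- as.numeric(Matrix::rowSums(expm1(mo))) / length(cells_out)
    avg_logfc <- log(mean_in + 1) - log(mean_out + 1)
    tested <- pmax(pct1, pct2) >= min_pct
    tested <- tested & if (positive_only) avg_logfc >= logfc_prefilter
                       else abs(avg_logfc) >= logfc_prefilter
    p <- rep(1, nrow(norm))
    if (any(tested)) {
        xi <- as.matrix(mi[tested, , drop = FALSE])
        xo <- as.matrix(mo[tested, , drop = FALSE])
        p[tested] <- vapply(seq_len(nrow(xi)), function(g)
            wilcox.test(xi[g, ], xo[g, ], exact = FALSE,
                        correct = TRUE)$p.value, 0)
    }
    padj <- if (adjust_method == "bonferroni") pmin(1, p * nrow(norm))
            else p.adjust(p, method = "BH")
    padj[!tested] <- 1
    passes <- tested & padj < padj_max & avg_logfc > logfc_min &
        pct1 > pct_in_min & pct2 < pct_out_max
    data.frame(gene_id = rownames(norm), p_value = p,
               avg_logfc = avg_logfc, pct_1 = pct1, pct_2 = pct2,
               p_adjusted = padj, tested = tested,
               passes_marker_criteria = passes,
               stringsAsFactors = FALSE, row.names = NULL)
}

#' Pairwise marker test between two populations
#'
#' Runs [wilcoxonMarkerTest()] in both orientations (each population in
#' turn as the focal group against the other).
#'
#' @param norm normalized matrix.
#' @param labels cell label data.frame (`cell_id`, `cluster`).
#' @param pop_a,pop_b cluster names; both must be present.
#' @param ... thresholds passed to [wilcoxonMarkerTest()].
#' @return MarkerStat data.frame with `group_in` and `group_out` columns.
#' @export
pairwiseMarkers <- function(norm, labels, pop_a, pop_b, ...) {
    for (p in c(pop_a, pop_b))
        if (!p %in% labels$cluster) stop("cluster absent: ", p)
    cells <- split(labels$cell_id, labels$cluster)
    out <- list()
    for (ori in list(c(pop_a, pop_b), c(pop_b, pop_a))) {
        ms <- wilcoxonMarkerTest(norm, cells[[ori[1]]], cells[[ori[2]]], ...)
        ms$group_in <- ori[1]
        ms$group_out <- ori[2]
        out[[ori[1]]] <- ms
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' One-vs-rest marker test for every cluster
#'
#' For each cluster, [wilcoxonMarkerTest()] against all remaining cells
#' pooled. Clusters with fewer than 3 cells are skipped with a warning.
#'
#' @param norm normalized matrix.
#' @param labels cell label data.frame (`cell_id`, `cluster`).
#' @param ... thresholds passed to [wilcoxonMarkerTest()].
#' @return MarkerStat data.frame with a `cluster` column.
#' @export
oneVsRestMarkers <- function(norm, labels, ...) {
    cl <- unique(labels$cluster)
    if (length(cl) < 2) stop("need at least 2 clusters")
    out <- list()
    for (ci in cl) {
        cin <- labels$cell_id[labels$cluster == ci]
        if (length(cin) < 3) {
            warning("cluster '", ci, "' has fewer than 3 cells; skipped")
            next
        }
        cout <- labels$cell_id[labels$cluster != ci]
        ms <- wilcoxonMarkerTest(norm, cin, cout, ...)
        ms$cluster <- ci
        out[[ci]] <- ms
    }
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}
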