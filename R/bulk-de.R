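#' @importFrom stats p.adjust pnorm pt hclust cutree dist sd
NULL

#' Median-of-ratios size factors
#'
#' For each sample, the median over all-positive genes of the ratio of its
#' count to the gene's geometric mean across samples, rescaled so the size
#' factors have geometric mean 1.
#'
#' @param counts bulk [CountMatrix-class] or count matrix.
#' @return named positive numeric vector, one per sample.
#' @export
bulkSizeFactors <- function(counts) {
    m <- if (is(counts, "CountMatrix")) as.matrix(counts(counts)) else counts
    logg <- rowMeans(log(m))
    ok <- is.finite(logg)
    if (!any(ok))
        stop("no gene with positive counts in every sample; ",
             "a pseudo-reference fallback would be required")
    gm <- exp(logg)
    s <- apply(m, 2, function(col) median(col[ok] / gm[ok]))
    s / exp(mean(log(s)))
}

#' Two-group negative-binomial Wald differential expression
#'
#' Counts are normalized by [bulkSizeFactors()]; genes whose total raw count
#' across all samples falls below `low_count_min` are excluded before
#' testing and classed `low_count_excluded`. For each tested gene the
#' per-group means of normalized counts give
#' `log2FC = log2((mB + c)/(mA + c))` with pseudocount `c` (normalized
#' units); the gene-wise dispersion is a method-of-moments estimate pooled
#' within groups, squeezed toward the across-gene median with `prior_df`
#' pseudo-degrees of freedom (a constant-target moderation that tames the
#' 2-df-per-group estimate at triplicate scale; no trend is fitted), and
#' floored; the standard error follows by the delta method from the NB
#' variance `mu + alpha mu^2`; the Wald statistic is referred to a t
#' distribution with `nA + nB - 2 + prior_df` degrees of freedom, which
#' keeps the test calibrated with the noisy plug-in variance;
#' Benjamini-Hochberg adjusts across all tested genes.
#'
#' The fold-change direction convention is condition B over condition A, so
#' genes higher in A carry negative log2FC (fold change below 1).
#'
#' @param counts bulk [CountMatrix-class] or count matrix.
#' @param groups two-level factor (or character) over the samples; the first
#'   level is condition A.
#' @param low_count_min minimum total raw count, default 10 (genes with
#'   fewer reads in total are not taken into account).
#' @param pseudocount added to group means before the log ratio, default 0.5
#'   normalized units.
#' @param alpha_floor dispersion floor, default 1e-8.
#' @param prior_df pseudo-degrees of freedom of the constant-target
#'   dispersion moderation, default 4; 0 disables it.
#' @return data.frame (`BulkDEResult`): `gene_id`, `base_mean`,
#'   `log2_fold_change`, `fold_change`, `p_value`, `p_adjusted`,
#'   `enrichment_class` (filled by [classifyEnrichment()];
#'   `low_count_excluded` or `not_significant` here).
#' @export
nbWaldTest <- function(counts, groups, low_count_min = 10,
                       pseudocount = 0.5, alpha_floor = 1e-8,
                       prior_df = 4) {
    m <- if (is(counts, "CountMatrix")) as.matrix(counts(counts)) else counts
    groups <- factor(groups)
    if (nlevels(groups) != 2) stop("groups must have exactly two levels")
    if (any(table(groups) < 2))
        stop("each group needs at least 2 samples")
    A <- groups == levels(groups)[1]
    B <- !A
    nA <- sum(A); nB <- sum(B)
    tested <- rowSums(m) >= low_count_min
    sf <- bulkSizeFactors(m)
    norm <- sweep(m, 2, sf, `/`)
    base_mean <- rowMeans(norm)
    mA <- rowMeans(norm[, A, drop = FALSE])
    mB <- rowMeans(norm[, B, drop = FALSE])
    vA <- apply(norm[, A, drop = FALSE], 1, var)
    vB <- apply(norm[, B, drop = FALSE], 1, var)
    aA <- (vA - mA) / mA^2
    aB <- (vB - mB) / mB^2
    df <- nA + nB - 2
    alpha <- ((nA - 1) * aA + (nB - 1) * aB) / df
    alpha[!is.finite(alpha)] <- 0
    if (prior_df > 0) {
        pos <- alpha[tested] > 0
        if (any(pos)) {
            alpha0 <- median(alpha[tested][pos])
            alpha <- (prior_df * alpha0 + df * alpha) / (prior_df + df)
            df <- df + prior_df
        }
    }
    alpha <- pmax(alpha, alpha_floor)
    lfc <- log2((mB + pseudocount) / (mA + pseudocount))
    se <- sqrt((mA + alpha * mA^2) / (nA * (mA + pseudocount)^2) +
               (mB + alpha * mB^2) / (nB * (mB + pseudocount)^2)) / log(2)
    z <- ifelse(se > 0, lfc / se, 0)
    p <- 2 * pt(-abs(z), df = df)
    res <- data.frame(gene_id = rownames(m),
                      base_mean = base_mean,
                      log2_fold_change = lfc,
                      fold_change = 2^lfc,
                      p_value = p,
                      p_adjusted = NA_real_,
                      enrichment_class = ifelse(tested, "not_significant",
                                                "low_count_excluded"),
                      stringsAsFactors = FALSE, row.names = NULL)
    res$p_value[!tested] <- NA_real_
    res$p_adjusted[tested] <- p.adjust(res$p_value[tested], method = "BH")
    res
}

#' Classify DE enrichment
#'
#' A gene is enriched in condition A when `p_adjusted < padj_max` and
#' `fold_change < fc_low`, in condition B when `p_adjusted < padj_max` and
#' `fold_change > fc_high`; otherwise `not_significant`. All inequalities
#' are strict; `low_count_excluded` genes are left untouched.
#'
#' @param results a [nbWaldTest()] table.
#' @param padj_max adjusted-p cutoff, default 0.01.
#' @param fc_high,fc_low fold-change bounds, defaults 2 and 0.5.
#' @return the table with `enrichment_class` filled
#'   (`A_enriched`/`B_enriched`/`not_significant`/`low_count_excluded`).
#' @export
classifyEnrichment <- function(results, padj_max = 0.01, fc_high = 2,
                               fc_low = 0.5) {
    cls <- results$enrichment_class
    tested <- cls != "low_count_excluded"
    sig <- tested & !is.na(results$p_adjusted) &
        results$p_adjusted < padj_max
    cls[tested] <- "not_significant"
    cls[sig & results$fold_change < fc_low] <- "A_enriched"
    cls[sig & results$fold_change > fc_high] <- "B_enriched"
    results$enrichment_class <- cls
    results
}

#' Convert log2 fold change to fold change
#' @param log2fc numeric.
#' @return `2^log2fc`.
#' @export
log2fcToFc <- function(log2fc) 2^log2fc

#' Hierarchical clustering of DE genes into expression-pattern groups
#'
#' Rows (genes) are z-scored across samples, clustered by Euclidean
#' distance with Ward linkage (`ward.D2`), and the tree is cut into exactly
#' `k` groups. Genes with zero variance across samples cannot be z-scored;
#' they are assigned to the nearest cluster centroid afterwards and flagged.
#' Genes are processed in `gene_id` order so the assignment is deterministic.
#'
#' @param mat expression matrix (RPKM or normalized counts), genes x samples.
#' @param de_genes gene ids to cluster (must number at least `k`).
#' @param k number of groups, default 15.
#' @return data.frame with `gene_id`, `cluster_index`, `zero_variance` flag.
#' @export
clusterDeGenes <- function(mat, de_genes, k = 15) {
    de_genes <- sort(unique(de_genes))
    if (length(de_genes) < k)
        stop("need at least k = ", k, " DE genes")
    if (ncol(mat) < 2) stop("need at least 2 samples")
    if (!all(de_genes %in% rownames(mat)))
        stop("de_genes absent from the matrix")
    x <- mat[de_genes, , drop = FALSE]
    sds <- apply(x, 1, sd)
    flat <- sds == 0
    z <- (x - rowMeans(x)) / ifelse(sds == 0, 1, sds)
    usable <- rownames(z)[!flat]
    if (length(usable) < k)
        stop("fewer than k genes with non-zero variance")
    hc <- hclust(dist(z[usable, , drop = FALSE]), method = "ward.D2")
    grp <- cutree(hc, k = k)
    out <- data.frame(gene_id = de_genes,
                      cluster_index = NA_integer_,
                      zero_variance = flat, stringsAsFactors = FALSE,
                      row.names = NULL)
    out$cluster_index[!flat] <- unname(grp[de_genes[!flat]])
    if (any(flat)) {
        cent <- vapply(seq_len(k), function(ci)
            colMeans(z[usable[grp == ci], , drop = FALSE]),
            numeric(ncol(z)))
        for (g in which(flat)) {
            dd <- colSums((cent - z[de_genes[g], ])^2)
            out$cluster_index[g] <- which.min(dd)
        }
    }
    out
}
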