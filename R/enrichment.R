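#' @importFrom stats phyper
NULL

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric probability `P(X >= k)` for the overlap `k`
#' between the query and each gene set (sets are intersected with the
#' universe before testing), Benjamini-Hochberg adjusted across sets.
#'
#' @param query gene set of interest; must be contained in `universe`.
#' @param sets named list of member vectors (see [readGmt()]).
#' @param universe background gene vector.
#' @return data.frame: `set_name`, `set_size` (in-universe), `query_size`,
#'   `overlap_count`, `p_value`, `p_adjusted`.
#' @export
oraHypergeometric <- function(query, sets, universe) {
    universe <- unique(universe)
    if (!length(universe)) stop("empty universe")
    if (!all(query %in% universe))
        stop("query contains genes outside the universe")
    query <- unique(query)
    N <- length(universe)
    n <- length(query)
    res <- lapply(names(sets), function(nm) {
        s <- intersect(unique(sets[[nm]]), universe)
        K <- length(s)
        k <- length(intersect(s, query))
        p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
        data.frame(set_name = nm, set_size = K, query_size = n,
                   overlap_count = k, p_value = p,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, res)
    out$p_adjusted <- p.adjust(out$p_value, method = "BH")
    out
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score on a ranked
# statistic vector (descending) and hit indices into it. Returns the signed
# maximum deviation from zero.
gseaRunningSum <- function(stat_sorted, hit_idx, weight = 1) {
    N <- length(stat_sorted)
    Nh <- length(hit_idx)
    w <- abs(stat_sorted[hit_idx])^weight
    nr <- sum(w)
    if (nr == 0) return(0)
    step <- numeric(N)
    step[hit_idx] <- w / nr
    miss <- rep(1 / (N - Nh), N)
    miss[hit_idx] <- 0
    rs <- cumsum(step - miss)
    unname(rs[which.max(abs(rs))])
}

#' Pre-ranked gene set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov running-sum enrichment score over a
#' gene ranking (here typically mean RPKM), restricted to genes whose score
#' exceeds `min_score`, ties broken by gene id. Hit increments are
#' proportional to `score^weight`. The null is built by permuting gene
#' labels (`n_perm` draws of random same-size sets); NES divides each ES by
#' the mean magnitude of same-sign null scores, and the FDR q-value follows
#' the standard pooled positive/negative null procedure. Sets smaller than
#' `min_set_size` after intersection with the ranking, or spanning the whole
#' ranking, are skipped with a warning.
#'
#' @param ranking named numeric vector, gene -> score.
#' @param sets named list of member vectors.
#' @param min_score keep genes with score strictly above this (default 1,
#'   the expressed-gene convention of the ranking's RPKM scale).
#' @param weight hit-weight exponent, default 1.
#' @param n_perm label permutations, default 1000.
#' @param seed RNG seed for the permutations.
#' @param min_set_size default 5.
#' @param q_max significance callout threshold recorded in the output,
#'   default 0.25.
#' @return data.frame (`EnrichmentResult`): `set_name`, `size`,
#'   `enrichment_score`, `normalized_es`, `p_value`, `fdr_q`,
#'   `significant`.
#' @export
gseaPreranked <- function(ranking, sets, min_score = 1, weight = 1,
                          n_perm = 1000, seed = 1, min_set_size = 5,
                          q_max = 0.25) {
    keep <- ranking > min_score
    r <- ranking[keep]
    ord <- order(-r, names(r))
    r <- r[ord]
    N <- length(r)
    if (N < 2) stop("fewer than 2 genes above min_score")
    set.seed(seed)
    use <- list()
    for (nm in names(sets)) {
        idx <- which(names(r) %in% sets[[nm]])
        if (length(idx) < min_set_size || length(idx) >= N) {
            warning("set '", nm, "' skipped (size ", length(idx),
                    " after intersection)")
            next
        }
        use[[nm]] <- idx
    }
    if (!length(use))
        return(data.frame(set_name = character(), size = integer(),
                          enrichment_score = numeric(),
                          normalized_es = numeric(), p_value = numeric(),
                          fdr_q = numeric(), significant = logical(),
                          stringsAsFactors = FALSE))
    es <- vapply(use, function(idx) gseaRunningSum(r, idx, weight), 0)
    sizes <- lengths(use)
    # one null distribution per distinct set size
    null_by_size <- lapply(unique(sizes), function(sz)
        vapply(seq_len(n_perm), function(b)
            gseaRunningSum(r, sort(sample.int(N, sz)), weight), 0))
    names(null_by_size) <- as.character(unique(sizes))
    nes <- numeric(length(es))
    pval <- numeric(length(es))
    null_nes <- vector("list", length(es))
    for (i in seq_along(es)) {
        nulls <- null_by_size[[as.character(sizes[i])]]
        same <- nulls[sign(nulls) == sign(es[i])]
        denom <- if (length(same)) mean(abs(same)) else NA_real_
        nes[i] <- if (is.na(denom) || denom == 0) NA_real_
                  else es[i] / denom
        pval[i] <- if (length(same))
            (sum(abs(same) >= abs(es[i])) + 1) / (length(same) + 1) else 1
        pos <- nulls[nulls > 0]; neg <- nulls[nulls < 0]
        null_nes[[i]] <- c(if (length(pos)) pos / mean(pos),
                           if (length(neg)) neg / mean(abs(neg)))
    }
    pooled <- unlist(null_nes)
    fdr <- vapply(seq_along(es), function(i) {
        if (is.na(nes[i])) return(NA_real_)
        if (nes[i] >= 0) {
            num <- mean(pooled[pooled >= 0] >= nes[i])
            den <- mean(nes[!is.na(nes) & nes >= 0] >= nes[i])
        } else {
            num <- mean(pooled[pooled <= 0] <= nes[i])
            den <- mean(nes[!is.na(nes) & nes <= 0] <= nes[i])
        }
        if (is.na(num)) num <- 1
        min(1, max(0, num / max(den, .Machine$double.eps)))
    }, 0)
    data.frame(set_name = names(use), size = as.integer(sizes),
               enrichment_score = unname(es), normalized_es = unname(nes),
               p_value = unname(pval), fdr_q = unname(fdr),
               significant = !is.na(fdr) & fdr < q_max,
               stringsAsFactors = FALSE, row.names = NULL)
}
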