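# Integration of bulk enrichment with single-cell marker calls: the
# "enriched" then "specific" tiers, with machine-readable exclusion reasons.

#' Call population-enriched genes
#'
#' A gene is enriched for population P when it passes the pairwise
#' single-cell marker criteria with P as focal group and its bulk
#' `enrichment_class` matches P's declared direction. Candidates failing one
#' modality are kept with a machine-readable `exclusion_reason`:
#' `no_bulk_enrichment` (single-cell pass, bulk discordant or not
#' significant), `low_sc_expression` (bulk concordant but the in-population
#' detection fraction never clears 0.5 — the low-expression exclusion),
#' `fails_sc_criteria` (bulk concordant, detected, but failing another
#' single-cell criterion), or `absent_in_modality`.
#'
#' @param pairwise [pairwiseMarkers()] output (`group_in` column).
#' @param bulk a classified [nbWaldTest()] table ([classifyEnrichment()]).
#' @param direction_map named character vector mapping each population to
#'   its bulk class, e.g. `c(FLC = "A_enriched", ALC = "B_enriched")`.
#' @param pct_in_min the detection criterion used to label the
#'   low-expression exclusion, default 0.5.
#' @return data.frame (`SpecificityCall`): `gene_id`, `population`, `tier`
#'   (`enriched` or `excluded`), evidence flags `bulk_same_direction`,
#'   `pairwise_pass`, `one_vs_rest_pass` (NA until [callSpecific()]), and
#'   `exclusion_reason` (NA for enriched rows).
#' @export
callEnriched <- function(pairwise, bulk, direction_map, pct_in_min = 0.5) {
    stopifnot(is.data.frame(pairwise), "group_in" %in% names(pairwise))
    pops <- unique(pairwise$group_in)
    missing <- setdiff(pops, names(direction_map))
    if (length(missing))
        stop("population missing from direction map: ",
             paste(missing, collapse = ", "))
    out <- list()
    for (pop in pops) {
        sc <- pairwise[pairwise$group_in == pop, , drop = FALSE]
        want <- direction_map[[pop]]
        bulk_dir_genes <- bulk$gene_id[bulk$enrichment_class == want]
        cand <- union(sc$gene_id[sc$passes_marker_criteria], bulk_dir_genes)
        if (!length(cand)) next
        si <- match(cand, sc$gene_id)
        bi <- match(cand, bulk$gene_id)
        sc_pass <- !is.na(si) & sc$passes_marker_criteria[si]
        bulk_ok <- !is.na(bi) & bulk$enrichment_class[bi] == want
        reason <- rep(NA_character_, length(cand))
        reason[sc_pass & is.na(bi)] <- "absent_in_modality"
        reason[sc_pass & !is.na(bi) & !bulk_ok] <- "no_bulk_enrichment"
        low <- bulk_ok & !sc_pass & !is.na(si) & sc$pct_1[si] <= pct_in_min
        reason[low] <- "low_sc_expression"
        reason[bulk_ok & !sc_pass & !is.na(si) & !low] <- "fails_sc_criteria"
        reason[bulk_ok & is.na(si)] <- "absent_in_modality"
        out[[pop]] <- data.frame(
            gene_id = cand, population = pop,
            tier = ifelse(sc_pass & bulk_ok, "enriched", "excluded"),
            bulk_same_direction = bulk_ok, pairwise_pass = sc_pass,
            one_vs_rest_pass = NA, exclusion_reason = reason,
            stringsAsFactors = FALSE)
    }
    if (!length(out))
        return(data.frame(gene_id = character(), population = character(),
                          tier = character(), bulk_same_direction = logical(),
                          pairwise_pass = logical(),
                          one_vs_rest_pass = logical(),
                          exclusion_reason = character(),
                          stringsAsFactors = FALSE))
    do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Promote enriched genes to population-specific
#'
#' An enriched gene becomes `specific` when it also passes the one-vs-rest
#' marker criteria for its population's cluster, i.e. it is low in every
#' other cluster of the tissue; otherwise it stays `enriched` with
#' `exclusion_reason = "expressed_elsewhere"`. Genes never reaching the
#' enriched tier are passed through unchanged.
#'
#' @param enriched a [callEnriched()] table.
#' @param one_vs_rest [oneVsRestMarkers()] output (`cluster` column).
#' @param cluster_map optional named map population -> cluster name when the
#'   two vocabularies differ (default: identical names).
#' @return the table with `tier` in `{specific, enriched, excluded}`.
#' @export
callSpecific <- function(enriched, one_vs_rest, cluster_map = NULL) {
    if (!nrow(enriched)) return(enriched)
    stopifnot("cluster" %in% names(one_vs_rest))
    out <- enriched
    for (i in which(out$tier == "enriched")) {
        pop <- out$population[i]
        clu <- if (is.null(cluster_map)) pop else cluster_map[[pop]]
        ovr <- one_vs_rest[one_vs_rest$cluster == clu &
                           one_vs_rest$gene_id == out$gene_id[i], ,
                           drop = FALSE]
        pass <- nrow(ovr) > 0 && any(ovr$passes_marker_criteria)
        out$one_vs_rest_pass[i] <- pass
        if (pass) {
            out$tier[i] <- "specific"
        } else {
            out$exclusion_reason[i] <- "expressed_elsewhere"
        }
    }
    out
}

#' Summary counts and percentages
#'
#' Counts per specificity tier and population, counts per bulk class, and
#' percentages of the expression universe, with half-up rounding to one
#' decimal (`percentage_digits = 0` reproduces integer-printed figures).
#'
#' @param calls a [callSpecific()] table.
#' @param bulk a classified bulk DE table.
#' @param universe_size number of genes expressed in either condition;
#'   default: bulk genes not excluded for low counts.
#' @param percentage_digits decimals for percentages, default 1.
#' @return list with `universe`, `bulk_class_counts`, `pct_A_enriched`,
#'   `pct_B_enriched`, `n_de_total`, `pct_de_total`, and
#'   `tier_counts` (population x tier).
#' @export
reportCounts <- function(calls, bulk, universe_size = NULL,
                         percentage_digits = 1) {
    if (is.null(universe_size))
        universe_size <- sum(bulk$enrichment_class != "low_count_excluded")
    if (universe_size == 0) stop("empty gene universe")
    cls <- table(factor(bulk$enrichment_class,
                        levels = c("A_enriched", "B_enriched",
                                   "not_significant",
                                   "low_count_excluded")))
    n_de <- unname(cls["A_enriched"] + cls["B_enriched"])
    pct <- function(k) roundHalfUp(100 * k / universe_size,
                                   percentage_digits)
    tiers <- if (nrow(calls))
        table(calls$population, factor(calls$tier,
                                       levels = c("specific", "enriched",
                                                  "excluded")))
    else table(character(), character())
    list(universe = universe_size,
         bulk_class_counts = as.list(cls),
         n_de_total = as.integer(n_de),
         pct_de_total = pct(n_de),
         pct_A_enriched = pct(unname(cls["A_enriched"])),
         pct_B_enriched = pct(unname(cls["B_enriched"])),
         tier_counts = tiers)
}
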