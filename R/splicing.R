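# Summarization of differential-splicing event tables: significance filter,
# population assignment by the sign of the inclusion-level difference, event
# tallies and DE-overlap counts.

#' Filter significant splicing events
#'
#' Keeps events with `fdr <= fdr_max` (boundary inclusive).
#'
#' @param tables list of standardized event data.frames
#'   (see [readRmatsTables()]).
#' @param fdr_max default 0.05.
#' @return filtered list.
#' @export
filterSignificant <- function(tables, fdr_max = 0.05) {
    lapply(tables, function(t) t[t$fdr <= fdr_max, , drop = FALSE])
}

#' Assign events to populations by inclusion sign
#'
#' An event with positive inclusion-level difference belongs to the
#' population measured as sample 1 in the splicing run, a negative one to
#' the other; exact zeros are left unassigned with a warning. The sample
#' orientation is explicit configuration because the attribution rule is a
#' convention of the upstream run, not of the tables themselves.
#'
#' @param events one standardized event data.frame (or several rbound).
#' @param sample1_population,sample2_population cluster names.
#' @return the table with a `population` column (NA for zero differences).
#' @export
assignPopulation <- function(events, sample1_population,
                             sample2_population) {
    d <- events$inc_level_difference
    pop <- ifelse(d > 0, sample1_population,
                  ifelse(d < 0, sample2_population, NA_character_))
    if (anyNA(pop))
        warning(sum(is.na(pop)),
                " event(s) with zero inclusion difference left unassigned")
    events$population <- pop
    events
}

#' Summarize assigned splicing events
#'
#' Event-type counts and proportions per population, distinct spliced gene
#' sets (including the genes spliced in both populations), and per-population
#' overlap with supplied DE gene sets (DE genes carrying at least one
#' significant spliced event).
#'
#' @param events filtered and assigned events (single data.frame).
#' @param de_sets named list population -> DE gene-id vector.
#' @return list (`SplicingSummary`) with `event_counts` (population x type),
#'   `event_proportions`, `n_events`, `genes` (per-population gene-id list),
#'   `genes_both`, `n_genes`, `de_overlap` (named counts),
#'   `n_unassigned`.
#' @export
summarizeSplicing <- function(events, de_sets = list()) {
    assigned <- events[!is.na(events$population), , drop = FALSE]
    pops <- unique(assigned$population)
    tab <- table(factor(assigned$population, levels = pops),
                 factor(assigned$event_type, levels = .rmats_event_types))
    prop <- tab / pmax(1, rowSums(tab))
    genes <- lapply(split(assigned$gene_id, assigned$population), unique)
    genes <- genes[pops]
    both <- if (length(pops) == 2)
        intersect(genes[[1]], genes[[2]]) else character()
    overlap <- vapply(names(de_sets), function(p)
        if (p %in% names(genes))
            length(intersect(de_sets[[p]], genes[[p]])) else 0L,
        integer(1))
    list(event_counts = tab,
         event_proportions = prop,
         n_events = setNames(as.integer(rowSums(tab)), rownames(tab)),
         genes = genes,
         genes_both = both,
         n_genes = vapply(genes, length, integer(1)),
         de_overlap = overlap,
         n_unassigned = sum(is.na(events$population)))
}
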