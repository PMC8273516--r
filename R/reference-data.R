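# Loaders for the published reference values shipped with the package:
# the differential-expression statistics of the validated FLC- and
# ALC-specific marker genes and the headline summary counts of the fetal
# versus adult Leydig cell contrast. They serve as worked-example inputs
# for the fold-change and percentage arithmetic utilities.

#' Published marker-gene DE statistics
#'
#' Reference bulk differential-expression statistics (base mean, log2 fold
#' change, fold change, p, adjusted p) for the validated population-specific
#' marker genes of the fetal ("FLC", 9 genes) and adult ("ALC", 50 genes)
#' Leydig cell populations. The fold-change convention is adult over fetal,
#' so FLC markers carry negative log2 fold changes.
#'
#' @param population `"FLC"` or `"ALC"`.
#' @return data.frame with `gene`, `base_mean`, `log2_fold_change`,
#'   `fold_change`, `p_value`, `p_adjusted`.
#' @export
markerReferenceTable <- function(population = c("FLC", "ALC")) {
    population <- match.arg(population)
    f <- system.file("extdata",
                     if (population == "FLC") "flc_marker_stats.tsv"
                     else "alc_marker_stats.tsv",
                     package = "LeydigMarkers", mustWork = TRUE)
    readTsv(f)
}

#' Published summary counts of the Leydig-cell contrast
#'
#' Headline counts reported for the fetal versus adult Leydig cell
#' comparison: expressed-gene totals, DE gene counts, splicing event and
#' gene tallies, single-cell Leydig cell counts, and enriched/specific
#' marker counts. Used as inputs to the percentage arithmetic the summary
#' stage reproduces.
#'
#' @return named numeric vector.
#' @export
reportedStudyCounts <- function() {
    f <- system.file("extdata", "reported_counts.tsv",
                     package = "LeydigMarkers", mustWork = TRUE)
    tab <- readTsv(f)
    setNames(as.numeric(tab$value), tab$quantity)
}
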