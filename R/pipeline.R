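#' @importFrom jsonlite write_json
#' @importFrom yaml write_yaml
NULL

#' Pipeline configuration
#'
#' Every threshold of every stage is a named, defaulted parameter; nothing
#' is hard-coded downstream. Unknown arguments are rejected by the explicit
#' signature. The defaults are the analysis thresholds of the Leydig-cell
#' contrast the pipeline targets: adjusted p < 0.01 and fold change outside
#' the 0.5-2 band in bulk, `min.pct` 0.25 and average-logFC 0.25 prefilters with
#' pass criteria (adj p < 0.01, avg logFC > 0.5, pct.1 > 0.5, pct.2 < 0.25)
#' in single cell, splicing FDR 0.05, expressed-gene RPKM 1, density
#' bandwidth 500 on a 4096-point grid, 15 expression-pattern clusters, GSEA
#' q < 0.25.
#'
#' @param sim a [simulationConfig()] describing the synthetic inputs.
#' @param padj_max,fc_high,fc_low,low_count_min bulk DE thresholds.
#' @param min_pct,logfc_prefilter single-cell test prefilters.
#' @param marker_padj,marker_logfc,marker_pct_in,marker_pct_out single-cell
#'   marker pass criteria.
#' @param splicing_fdr splicing significance cutoff.
#' @param min_rpkm expressed-gene threshold.
#' @param density_bw,density_grid barcode-calling density parameters.
#' @param k_clusters DE expression-pattern cluster count.
#' @param gsea_q,gsea_nperm GSEA significance threshold and permutations.
#' @param run_barcodes,run_splicing,run_enrichment optional stage switches.
#' @param out_dir optional output directory; when given, every stage table,
#'   a `summary.json` and the resolved configuration (`config.yaml`) are
#'   written there.
#' @param seed master seed; overrides `sim$seed` so one integer drives the
#'   whole run.
#' @return a `PipelineConfig` list.
#' @export
pipelineConfig <- function(sim = simulationConfig(),
                           padj_max = 0.01, fc_high = 2, fc_low = 0.5,
                           low_count_min = 10,
                           min_pct = 0.25, logfc_prefilter = 0.25,
                           marker_padj = 0.01, marker_logfc = 0.5,
                           marker_pct_in = 0.5, marker_pct_out = 0.25,
                           splicing_fdr = 0.05, min_rpkm = 1,
                           density_bw = 500, density_grid = 4096,
                           k_clusters = 15,
                           gsea_q = 0.25, gsea_nperm = 200,
                           run_barcodes = TRUE, run_splicing = TRUE,
                           run_enrichment = TRUE,
                           out_dir = NULL, seed = 1L) {
    cfg <- as.list(environment())
    cfg$sim$seed <- as.integer(seed)
    class(cfg) <- "PipelineConfig"
    cfg
}

#' Run the full synthetic analysis pipeline
#'
#' Generates the synthetic dataset with planted truth, then executes:
#' optional barcode calling; RPKM quantification with expressed-gene,
#' biotype and correlation accounting; bulk NB Wald differential expression
#' with enrichment classification and expression-pattern clustering;
#' single-cell pairwise and one-vs-rest marker statistics; the
#' enriched/specific integration; optional splicing summarization and
#' enrichment statistics. Results (and, with `out_dir`, all stage tables
#' plus a summary JSON) are returned; the run is a pure function of the
#' configuration seed.
#'
#' @param config a [pipelineConfig()].
#' @return (invisibly) list with all stage results, the planted `truth`,
#'   and `summary` (the counts the summary JSON carries).
#' @export
runPipeline <- function(config) {
    stopifnot(inherits(config, "PipelineConfig"))
    sim <- config$sim
    truth <- simulateTruth(sim)
    bulk <- simulateBulk(sim, truth)
    sc <- simulateSingleCell(sim, truth)
    conds <- unname(sim$condition_names)
    cond_of <- colData(bulk$counts)$condition

    calling <- NULL
    if (config$run_barcodes) {
        prof <- simulateBarcodeProfile(sim)
        calling <- callCells(prof, bandwidth = config$density_bw,
                             grid_points = config$density_grid)
    }

    rpkm <- computeRpkm(bulk$counts, bulk$annotation)
    expressed <- lapply(setNames(conds, conds), function(cc)
        expressedGenes(rpkm, samples = which(cond_of == cc),
                       min_rpkm = config$min_rpkm))
    universe <- union(expressed[[1]], expressed[[2]])
    biotypes <- biotypeProportions(rpkm, bulk$annotation)
    correlations <- sampleCorrelations(rpkm)

    de <- nbWaldTest(bulk$counts, groups = factor(cond_of, levels = conds),
                     low_count_min = config$low_count_min)
    de <- classifyEnrichment(de, padj_max = config$padj_max,
                             fc_high = config$fc_high,
                             fc_low = config$fc_low)
    de_sets <- list(
        de$gene_id[de$enrichment_class == "A_enriched"],
        de$gene_id[de$enrichment_class == "B_enriched"])
    names(de_sets) <- conds
    de_all <- unlist(de_sets, use.names = FALSE)
    de_clusters <- if (length(de_all) >= config$k_clusters)
        clusterDeGenes(rpkm, de_all, k = config$k_clusters) else NULL

    norm <- normalizeCells(sc$counts)
    marker_args <- list(min_pct = config$min_pct,
                        logfc_prefilter = config$logfc_prefilter,
                        padj_max = config$marker_padj,
                        logfc_min = config$marker_logfc,
                        pct_in_min = config$marker_pct_in,
                        pct_out_max = config$marker_pct_out)
    pairwise <- do.call(pairwiseMarkers,
                        c(list(norm, sc$labels, conds[1], conds[2]),
                          marker_args))
    one_vs_rest <- do.call(oneVsRestMarkers,
                           c(list(norm, sc$labels), marker_args))

    direction_map <- setNames(c("A_enriched", "B_enriched"), conds)
    calls <- callEnriched(pairwise, de, direction_map,
                          pct_in_min = config$marker_pct_in)
    calls <- callSpecific(calls, one_vs_rest)

    splicing <- NULL
    if (config$run_splicing) {
        tabs <- simulateSplicingTables(sim, de_sets)
        sig <- do.call(rbind, c(filterSignificant(tabs,
                                                  config$splicing_fdr),
                                list(make.row.names = FALSE)))
        sig <- assignPopulation(sig, conds[1], conds[2])
        splicing <- summarizeSplicing(sig, de_sets)
    }

    enrich <- NULL
    if (config$run_enrichment) {
        set.seed(childSeed(sim$seed, "genesets"))
        planted <- list()
        planted[[paste0(conds[1], "_program")]] <- truth$gene_id[
            truth$role == "bulk_de_up_A" |
            (truth$role == "specific_marker" & truth$target == conds[1])]
        planted[[paste0(conds[2], "_program")]] <- truth$gene_id[
            truth$role == "bulk_de_up_B" |
            (truth$role == "specific_marker" & truth$target == conds[2])]
        for (i in 1:3)
            planted[[paste0("random_set_", i)]] <-
                sample(truth$gene_id, 50)
        ora <- oraHypergeometric(
            intersect(de_sets[[1]], de$gene_id),
            planted, de$gene_id[de$enrichment_class !=
                                "low_count_excluded"])
        ranking <- setNames(rowMeans(rpkm), rownames(rpkm))
        gsea <- suppressWarnings(gseaPreranked(
            ranking, planted, min_score = config$min_rpkm,
            n_perm = config$gsea_nperm,
            seed = childSeed(sim$seed, "gsea"), q_max = config$gsea_q))
        enrich <- list(ora = ora, gsea = gsea)
    }

    report <- reportCounts(calls, de, universe_size = length(universe))
    summary <- list(
        seed = sim$seed,
        n_genes = sim$n_genes,
        n_cells = sum(sim$cell_counts_per_cluster),
        expressed_genes = vapply(expressed, length, integer(1)),
        universe = length(universe),
        de_counts = report$bulk_class_counts,
        n_de_total = report$n_de_total,
        pct_de_total = report$pct_de_total,
        pct_A_enriched = report$pct_A_enriched,
        pct_B_enriched = report$pct_B_enriched,
        enriched_counts = vapply(setNames(conds, conds), function(p)
            sum(calls$population == p & calls$tier %in%
                c("enriched", "specific")), integer(1)),
        specific_counts = vapply(setNames(conds, conds), function(p)
            sum(calls$population == p & calls$tier == "specific"),
            integer(1)),
        called_cells = if (is.null(calling)) NA_integer_
                       else calling$n_called,
        splicing_events = if (is.null(splicing)) NULL
                          else as.list(splicing$n_events),
        splicing_de_overlap = if (is.null(splicing)) NULL
                              else as.list(splicing$de_overlap))

    res <- list(config = config, truth = truth, bulk = bulk, sc = sc,
                rpkm = rpkm, expressed = expressed, biotypes = biotypes,
                correlations = correlations, de = de,
                de_clusters = de_clusters, pairwise = pairwise,
                one_vs_rest = one_vs_rest, calls = calls,
                calling = calling, splicing = splicing,
                enrichment = enrich, summary = summary)

    if (!is.null(config$out_dir)) writePipelineOutputs(res, config$out_dir)
    invisible(res)
}

# Stage tables, summary.json and the resolved config, written to out_dir.
writePipelineOutputs <- function(res, out_dir) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    conds <- unname(res$config$sim$condition_names)
    de_out <- data.frame(
        Gene = res$de$gene_id,
        `Base mean` = res$de$base_mean,
        log2FoldChange = res$de$log2_fold_change,
        `Fold change` = res$de$fold_change,
        `p-value` = res$de$p_value,
        `p-adj` = res$de$p_adjusted,
        class = res$de$enrichment_class,
        check.names = FALSE)
    writeTsv(de_out, file.path(out_dir, "bulk_de.tsv"))
    writeTsv(res$pairwise, file.path(out_dir, "pairwise_markers.tsv"))
    writeTsv(res$one_vs_rest, file.path(out_dir, "one_vs_rest_markers.tsv"))
    for (pop in conds) {
        for (tier in c("enriched", "specific")) {
            keep <- res$calls$population == pop &
                (if (tier == "enriched")
                     res$calls$tier %in% c("enriched", "specific")
                 else res$calls$tier == "specific")
            sub <- merge(res$calls[keep, ], de_out,
                         by.x = "gene_id", by.y = "Gene")
            writeTsv(sub, file.path(out_dir,
                                    paste0(tier, "_", pop, ".tsv")))
        }
    }
    writeTsv(res$calls[res$calls$tier == "excluded", ],
             file.path(out_dir, "exclusions.tsv"))
    if (!is.null(res$calling)) {
        writeLines(res$calling$called_barcodes,
                   file.path(out_dir, "called_barcodes.txt"))
        writeTsv(res$calling$density_grid,
                 file.path(out_dir, "density_grid.tsv"))
    }
    write_json(res$summary, file.path(out_dir, "summary.json"),
               auto_unbox = TRUE, digits = NA, pretty = TRUE)
    cfg <- res$config
    cfg$sim <- unclass(cfg$sim)
    cfg$sim$splicing_sig_counts <-
        lapply(cfg$sim$splicing_sig_counts, as.list)
    write_yaml(lapply(unclass(cfg), function(x)
        if (is.null(x)) "" else x), file.path(out_dir, "config.yaml"))
    invisible(out_dir)
}

#' Score specificity calls against planted truth
#'
#' @param calls a [callSpecific()] table.
#' @param truth a [simulateTruth()] table.
#' @return list: `recall` (fraction of planted specific markers called
#'   specific for their own population), `n_planted`, `n_recovered`,
#'   `trap_specific` (trap genes wrongly called specific),
#'   `null_specific` (planted-null genes called specific),
#'   `trap_low_reason_ok` and `trap_no_bulk_reason_ok` (traps excluded with
#'   the expected machine-readable reason).
#' @export
evaluateCalls <- function(calls, truth) {
    planted <- truth[truth$role == "specific_marker", ]
    hit <- vapply(seq_len(nrow(planted)), function(i)
        any(calls$gene_id == planted$gene_id[i] &
            calls$population == planted$target[i] &
            calls$tier == "specific"), logical(1))
    spec_genes <- calls$gene_id[calls$tier == "specific"]
    traps <- truth$gene_id[truth$role %in%
                           c("trap_low_expression",
                             "trap_no_bulk_enrichment")]
    nulls <- truth$gene_id[truth$role == "null"]
    reason_of <- function(ids)
        vapply(ids, function(g) {
            r <- calls$exclusion_reason[calls$gene_id == g]
            r <- r[!is.na(r)]
            if (length(r)) r[1] else NA_character_
        }, "")
    tl <- truth$gene_id[truth$role == "trap_low_expression"]
    tn <- truth$gene_id[truth$role == "trap_no_bulk_enrichment"]
    list(recall = mean(hit), n_planted = nrow(planted),
         n_recovered = sum(hit),
         trap_specific = sum(traps %in% spec_genes),
         null_specific = sum(nulls %in% spec_genes),
         trap_low_reason_ok =
             sum(reason_of(tl) == "low_sc_expression", na.rm = TRUE),
         trap_no_bulk_reason_ok =
             sum(reason_of(tn) == "no_bulk_enrichment", na.rm = TRUE))
}
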