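#' @importFrom stats rlnorm rnbinom rmultinom runif rnorm setNames
NULL

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Defaults mirror the
#' study design the pipeline targets: two bulk conditions (fetal and adult
#' Leydig cells, "FLC"/"ALC") in biological triplicate with negative-binomial
#' counts; a merged two-stage single-cell matrix with roughly 150 cells per
#' Leydig cluster among other testicular cell types; and a droplet barcode
#' profile with 500 cell-containing barcodes over an ambient mode.
#'
#' @param n_genes number of genes.
#' @param n_replicates_per_condition bulk replicates per condition.
#' @param condition_names names of bulk condition A and B (A is the fetal
#'   population; the bulk fold-change convention is B over A).
#' @param cell_counts_per_cluster named integer vector of cells per cluster.
#' @param cluster_stages named character vector mapping each cluster to
#'   `"fetal"` or `"adult"`.
#' @param nb_dispersion bulk negative-binomial dispersion (variance
#'   mu + dispersion * mu^2).
#' @param size_factor_sdlog sdlog of the log-normal per-sample size factors.
#' @param de_mean_range range of the baseline (lower-group) mean for genes
#'   with a planted bulk effect; the up-regulated group mean is
#'   `2^|planted_log2fc|` times larger. The 200-count floor keeps planted
#'   effects in the regime where a triplicate NB test has power.
#' @param planted_log2fc magnitude of planted bulk log2 fold changes.
#' @param planted_pct_in,planted_pct_out target detection fractions of a
#'   planted marker inside / outside its cluster.
#' @param trap_pct_in in-cluster detection fraction of the low-expression
#'   trap genes (must be < 0.5, the pct.1 criterion they are built to fail).
#' @param n_specific_markers,n_trap_low,n_trap_no_bulk named counts (per
#'   Leydig population) of planted specific markers and trap genes.
#' @param n_bulk_de named counts of bulk-only DE genes up in A / up in B.
#' @param n_cluster_markers planted one-cluster markers per non-Leydig
#'   cluster.
#' @param protein_coding_fraction fraction of genes annotated protein_coding.
#' @param cell_umi_mean,cell_umi_sdlog log-normal UMI-total parameters of
#'   cell-containing barcodes (also the single-cell library-size model).
#' @param ambient_umi_mean,ambient_umi_sdlog same for empty droplets.
#' @param n_cell_barcodes,n_empty_barcodes barcode counts for the droplet
#'   profile.
#' @param splicing_sig_counts list (per population) of named significant
#'   event counts by type; the default skews intron retention (RI) toward the
#'   fetal population, the event-class imbalance the summary stage reports.
#' @param splicing_nonsig_per_type background non-significant events per type.
#' @param splicing_de_overlap fraction of each population's DE genes given a
#'   significant splicing event.
#' @param seed master integer seed; per-stage child seeds derive from it.
#' @return a `SimulationConfig` list.
#' @export
simulationConfig <- function(
        n_genes = 2000L,
        n_replicates_per_condition = 3L,
        condition_names = c(A = "FLC", B = "ALC"),
        cell_counts_per_cluster = c(FLC = 151L, ALC = 148L,
                                    FetalSertoli = 150L, Interstitial = 120L,
                                    AdultSertoli = 180L, Germ = 200L),
        cluster_stages = c(FLC = "fetal", FetalSertoli = "fetal",
                           Interstitial = "fetal", ALC = "adult",
                           AdultSertoli = "adult", Germ = "adult"),
        nb_dispersion = 0.05,
        size_factor_sdlog = 0.1,
        de_mean_range = c(200, 2000),
        planted_log2fc = 3,
        planted_pct_in = 0.9,
        planted_pct_out = 0.02,
        trap_pct_in = 0.3,
        n_specific_markers = c(FLC = 15L, ALC = 15L),
        n_trap_low = c(FLC = 5L, ALC = 5L),
        n_trap_no_bulk = c(FLC = 5L, ALC = 5L),
        n_bulk_de = c(A = 150L, B = 150L),
        n_cluster_markers = 10L,
        protein_coding_fraction = 0.785,
        cell_umi_mean = 8000,
        cell_umi_sdlog = 0.25,
        ambient_umi_mean = 200,
        ambient_umi_sdlog = 0.5,
        n_cell_barcodes = 500L,
        n_empty_barcodes = 50000L,
        splicing_sig_counts = list(
            FLC = c(SE = 430L, RI = 742L, A3SS = 90L, A5SS = 60L, MXE = 58L),
            ALC = c(SE = 380L, RI = 34L, A3SS = 80L, A5SS = 50L, MXE = 47L)),
        splicing_nonsig_per_type = 200L,
        splicing_de_overlap = 0.1,
        seed = 1L) {
    cfg <- as.list(environment())
    stopifnot(cfg$n_genes > 0, cfg$n_replicates_per_condition > 0,
              all(cfg$cell_counts_per_cluster > 0),
              cfg$nb_dispersion > 0, cfg$cell_umi_mean > 0,
              cfg$ambient_umi_mean > 0,
              cfg$n_cell_barcodes > 0, cfg$n_empty_barcodes > 0,
              cfg$trap_pct_in < 0.5)
    if (!setequal(names(cfg$cluster_stages),
                  names(cfg$cell_counts_per_cluster)))
        stop("cluster_stages and cell_counts_per_cluster name different clusters")
    class(cfg) <- "SimulationConfig"
    cfg
}

#' Generate the planted ground-truth table
#'
#' Assigns exactly one role to each gene: population-specific markers
#' (concordant bulk and single-cell effects), two kinds of trap genes built
#' to be excluded by specific filters (low single-cell detection; no bulk
#' enrichment), bulk-only DE genes, non-Leydig cluster markers, and nulls.
#'
#' @param config a [simulationConfig()].
#' @return data.frame with `gene_id`, `gene_symbol`, `role`, `target`
#'   (cluster for single-cell roles, NA otherwise), `planted_log2fc`
#'   (condition B over A), `planted_pct_in`, `planted_pct_out`.
#' @export
simulateTruth <- function(config) {
    n <- config$n_genes
    ids <- sprintf("G%05d", seq_len(n))
    truth <- data.frame(gene_id = ids,
                        gene_symbol = sprintf("Gene%05d", seq_len(n)),
                        role = "null", target = NA_character_,
                        planted_log2fc = 0,
                        planted_pct_in = NA_real_,
                        planted_pct_out = NA_real_,
                        stringsAsFactors = FALSE)
    pops <- config$condition_names  # c(A=..., B=...)
    lfc_for <- function(pop) {
        if (pop == pops[["A"]]) -config$planted_log2fc
        else config$planted_log2fc
    }
    i <- 1L
    take <- function(k) {
        idx <- seq.int(i, length.out = k)
        i <<- i + k
        idx
    }
    for (pop in pops) {
        idx <- take(config$n_specific_markers[[pop]])
        truth$role[idx] <- "specific_marker"
        truth$target[idx] <- pop
        truth$planted_log2fc[idx] <- lfc_for(pop)
        truth$planted_pct_in[idx] <- config$planted_pct_in
        truth$planted_pct_out[idx] <- config$planted_pct_out
    }
    for (pop in pops) {
        idx <- take(config$n_trap_low[[pop]])
        truth$role[idx] <- "trap_low_expression"
        truth$target[idx] <- pop
        truth$planted_log2fc[idx] <- lfc_for(pop)
        truth$planted_pct_in[idx] <- config$trap_pct_in
        truth$planted_pct_out[idx] <- config$planted_pct_out
    }
    for (pop in pops) {
        idx <- take(config$n_trap_no_bulk[[pop]])
        truth$role[idx] <- "trap_no_bulk_enrichment"
        truth$target[idx] <- pop
        truth$planted_log2fc[idx] <- 0
        truth$planted_pct_in[idx] <- config$planted_pct_in
        truth$planted_pct_out[idx] <- config$planted_pct_out
    }
    idx <- take(config$n_bulk_de[["A"]])
    truth$role[idx] <- "bulk_de_up_A"
    truth$planted_log2fc[idx] <- -config$planted_log2fc
    idx <- take(config$n_bulk_de[["B"]])
    truth$role[idx] <- "bulk_de_up_B"
    truth$planted_log2fc[idx] <- config$planted_log2fc
    other <- setdiff(names(config$cell_counts_per_cluster), pops)
    for (cl in other) {
        idx <- take(config$n_cluster_markers)
        truth$role[idx] <- "sc_marker"
        truth$target[idx] <- cl
        truth$planted_pct_in[idx] <- config$planted_pct_in
        truth$planted_pct_out[idx] <- config$planted_pct_out
    }
    if (i - 1L > n) stop("n_genes too small for the requested planted roles")
    truth
}

#' Simulate a bulk count matrix with annotation
#'
#' Gene-wise negative-binomial counts with per-sample log-normal size
#' factors; genes with a planted effect have condition means differing by
#' `2^planted_log2fc`, with the high-side mean drawn from
#' `config$de_mean_range`. Gene lengths are uniform in 500-10,000 bp and
#' biotypes follow `protein_coding_fraction`.
#'
#' @param config a [simulationConfig()].
#' @param truth a [simulateTruth()] table covering all genes.
#' @return list with `counts` (a bulk [CountMatrix-class] whose `colData`
#'   carries `condition`) and `annotation`.
#' @export
simulateBulk <- function(config, truth) {
    if (config$n_replicates_per_condition < 2)
        stop("at least 2 replicates per condition are required for DE")
    if (nrow(truth) != config$n_genes)
        stop("truth table does not cover all genes")
    set.seed(childSeed(config$seed, "bulk"))
    n <- config$n_genes
    nrep <- config$n_replicates_per_condition
    lfc <- truth$planted_log2fc
    mu0 <- rlnorm(n, log(150), 1)
    base <- runif(n, config$de_mean_range[1], config$de_mean_range[2])
    muA <- ifelse(lfc < 0, base * 2^(-lfc), ifelse(lfc > 0, base, mu0))
    muB <- ifelse(lfc > 0, base * 2^lfc, ifelse(lfc < 0, base, mu0))
    conds <- rep(config$condition_names, each = nrep)
    sf <- rlnorm(2 * nrep, 0, config$size_factor_sdlog)
    mu <- cbind(matrix(muA, n, nrep), matrix(muB, n, nrep))
    mu <- sweep(mu, 2, sf, `*`)
    m <- matrix(rnbinom(n * 2 * nrep, mu = as.vector(mu),
                        size = 1 / config$nb_dispersion), n, 2 * nrep)
    dimnames(m) <- list(truth$gene_id,
                        paste0(conds, "_", rep(seq_len(nrep), 2)))
    annotation <- data.frame(
        gene_id = truth$gene_id,
        gene_symbol = truth$gene_symbol,
        length_bp = sample(500:10000, n, replace = TRUE),
        biotype = sample(c("protein_coding", "lncRNA"), n, replace = TRUE,
                         prob = c(config$protein_coding_fraction,
                                  1 - config$protein_coding_fraction)),
        stringsAsFactors = FALSE)
    cm <- CountMatrix(m, "bulk", annotation = annotation)
    colData(cm)$condition <- conds
    metadata(cm)$seed <- config$seed
    list(counts = cm, annotation = annotation)
}

#' Simulate a labeled single-cell UMI matrix
#'
#' Per-cell counts are multinomial draws over a cluster-specific expression
#' profile with log-normal library sizes around `cell_umi_mean`. A planted
#' marker's profile weight in its cluster is chosen so that the expected
#' per-cell detection fraction equals `planted_pct_in` at the mean library
#' size (and `planted_pct_out` elsewhere); low-expression trap genes get an
#' in-cluster detection below 0.5 while keeping their strong bulk effect.
#'
#' @param config a [simulationConfig()].
#' @param truth a [simulateTruth()] table.
#' @return list with `counts` (single-cell [CountMatrix-class], sparse, with
#'   `cluster` and `stage` in `colData`) and `labels` (data.frame
#'   `cell_id`/`cluster`/`stage`).
#' @export
simulateSingleCell <- function(config, truth) {
    clusters <- names(config$cell_counts_per_cluster)
    targets <- unique(truth$target[!is.na(truth$target)])
    missing <- setdiff(targets, clusters)
    if (length(missing))
        stop("truth names cluster(s) absent from cell_counts_per_cluster: ",
             paste(missing, collapse = ", "))
    for (st in unique(config$cluster_stages))
        if (sum(config$cluster_stages == st) < 2)
            stop("need at least 2 clusters per stage (", st, ")")
    set.seed(childSeed(config$seed, "single_cell"))
    n <- config$n_genes
    L0 <- config$cell_umi_mean
    base <- rlnorm(n, 0, 1.5)
    base <- base / sum(base)
    prob <- matrix(base, n, length(clusters),
                   dimnames = list(truth$gene_id, clusters))
    q_of <- function(pct) -log(1 - pct) / L0
    scroles <- c("specific_marker", "trap_low_expression",
                 "trap_no_bulk_enrichment", "sc_marker")
    planted <- which(truth$role %in% scroles)
    for (g in planted) {
        prob[g, ] <- q_of(truth$planted_pct_out[g])
        prob[g, truth$target[g]] <- q_of(truth$planted_pct_in[g])
    }
    prob <- sweep(prob, 2, Matrix::colSums(prob), `/`)
    ncell <- sum(config$cell_counts_per_cluster)
    cl_of_cell <- rep(clusters, config$cell_counts_per_cluster)
    libsize <- pmax(100, round(rlnorm(ncell, log(L0),
                                      config$cell_umi_sdlog)))
    m <- matrix(0L, n, ncell)
    for (c_i in seq_len(ncell))
        m[, c_i] <- rmultinom(1, libsize[c_i], prob[, cl_of_cell[c_i]])
    cell_ids <- sprintf("cell%05d", seq_len(ncell))
    dimnames(m) <- list(truth$gene_id, cell_ids)
    sm <- as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
    cm <- CountMatrix(sm, "single_cell")
    colData(cm)$cluster <- cl_of_cell
    colData(cm)$stage <- unname(config$cluster_stages[cl_of_cell])
    metadata(cm)$seed <- config$seed
    labels <- data.frame(cell_id = cell_ids, cluster = cl_of_cell,
                         stage = unname(config$cluster_stages[cl_of_cell]),
                         stringsAsFactors = FALSE)
    list(counts = cm, labels = labels)
}

#' Simulate a ranked droplet barcode profile
#'
#' Pools `n_cell_barcodes` log-normal UMI totals around `cell_umi_mean` with
#' `n_empty_barcodes` around `ambient_umi_mean`. The true number of
#' cell-containing barcodes is stored in the `true_cells` attribute. A
#' configuration whose modes are not separable (`ambient >= cell/5`) is
#' flagged in the `separable` attribute rather than rejected.
#'
#' @param config a [simulationConfig()].
#' @return a barcode-rank profile (see [barcodeRankProfile()]).
#' @export
simulateBarcodeProfile <- function(config) {
    set.seed(childSeed(config$seed, "barcodes"))
    cells <- rlnorm(config$n_cell_barcodes, log(config$cell_umi_mean),
                    config$cell_umi_sdlog)
    empties <- rlnorm(config$n_empty_barcodes, log(config$ambient_umi_mean),
                      config$ambient_umi_sdlog)
    umi <- pmax(1, round(c(cells, empties)))
    nbc <- length(umi)
    barcodes <- sprintf("BC%07d", sample.int(nbc))
    prof <- barcodeRankProfile(setNames(umi, barcodes))
    attr(prof, "true_cells") <- config$n_cell_barcodes
    sep <- config$ambient_umi_mean < config$cell_umi_mean / 5
    attr(prof, "separable") <- sep
    if (!sep)
        warning("ambient and cell UMI modes are not separable ",
                "(ambient_umi_mean >= cell_umi_mean / 5)")
    prof
}

#' Simulate rMATS-style differential-splicing tables
#'
#' Builds one table per event type with a significant mass (FDR uniform
#' below 0.05) split between the two populations per
#' `config$splicing_sig_counts`, signed inclusion-level differences
#' (population A events positive under the sample-1 = A orientation), and a
#' uniform non-significant background. A fraction `splicing_de_overlap` of
#' each population's DE genes is given a significant event.
#'
#' @param config a [simulationConfig()].
#' @param de_genes named list (per population) of DE gene-id vectors.
#' @return named list of standardized splicing event data.frames.
#' @export
simulateSplicingTables <- function(config, de_genes) {
    set.seed(childSeed(config$seed, "splicing"))
    pops <- unname(config$condition_names)
    sig <- config$splicing_sig_counts
    stopifnot(all(pops %in% names(sig)))
    rows <- list()
    for (pop in pops) {
        k_tot <- sum(sig[[pop]])
        n_de <- round(config$splicing_de_overlap *
                      length(de_genes[[pop]]))
        n_de <- min(n_de, k_tot)
        de_pick <- sample(de_genes[[pop]], n_de)
        pool_n <- max(1, ceiling(0.8 * (k_tot - n_de)))
        other_pool <- sprintf("SPL%s%05d", substr(pop, 1, 1), seq_len(pool_n))
        genes <- c(de_pick,
                   sample(other_pool, k_tot - n_de, replace = TRUE))
        genes <- sample(genes)
        types <- rep(names(sig[[pop]]), sig[[pop]])
        sgn <- if (pop == pops[1]) 1 else -1
        rows[[pop]] <- data.frame(
            event_type = types,
            gene_id = genes,
            gene_symbol = genes,
            fdr = runif(k_tot, 0, 0.05),
            inc_level_difference = sgn * runif(k_tot, 0.05, 0.9),
            stringsAsFactors = FALSE)
    }
    n_bg <- config$splicing_nonsig_per_type
    bg <- data.frame(
        event_type = rep(.rmats_event_types, each = n_bg),
        gene_id = sprintf("SPLBG%05d",
                          seq_len(n_bg * length(.rmats_event_types))),
        gene_symbol = sprintf("SPLBG%05d",
                              seq_len(n_bg * length(.rmats_event_types))),
        fdr = runif(n_bg * length(.rmats_event_types), 0.06, 1),
        inc_level_difference =
            runif(n_bg * length(.rmats_event_types), -0.9, 0.9),
        stringsAsFactors = FALSE)
    all_ev <- rbind(do.call(rbind, rows), bg)
    out <- split(all_ev, all_ev$event_type)
    out <- out[.rmats_event_types]
    lapply(out, function(d) { rownames(d) <- NULL; d })
}
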