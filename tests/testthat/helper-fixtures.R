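# Shared fixture builders. All data are generated in code at test time.

toyAnnotation <- function(ids, len = 1000L, biotype = "protein_coding") {
    data.frame(gene_id = ids, gene_symbol = paste0("Sym", ids),
               length_bp = rep_len(len, length(ids)),
               biotype = rep_len(biotype, length(ids)),
               stringsAsFactors = FALSE)
}

toyBulkMatrix <- function(nr = 3, nc = 2, values = seq_len(nr * nc)) {
    matrix(values, nr, nc,
           dimnames = list(sprintf("g%02d", seq_len(nr)),
                           sprintf("s%d", seq_len(nc))))
}

# A scaled-down simulation configuration for fast unit tests; the full-size
# defaults are exercised by the acceptance suite.
smallSimConfig <- function(seed = 1L, ...) {
    defaults <- list(
        n_genes = 400L,
        cell_counts_per_cluster = c(FLC = 60L, ALC = 60L,
                                    FetalSertoli = 40L, Interstitial = 40L,
                                    AdultSertoli = 40L, Germ = 40L),
        n_specific_markers = c(FLC = 5L, ALC = 5L),
        n_trap_low = c(FLC = 2L, ALC = 2L),
        n_trap_no_bulk = c(FLC = 2L, ALC = 2L),
        n_bulk_de = c(A = 30L, B = 30L),
        n_cluster_markers = 4L,
        n_empty_barcodes = 20000L,
        seed = seed)
    do.call(simulationConfig, utils::modifyList(defaults, list(...)))
}

# Two near-flat plateaus joined by a cliff: ~1000 "cell" barcodes around
# 10,000 UMI and ~100,000 ambient barcodes around 100. The tiny within-
# plateau slopes keep the log-log curvature well-defined.
twoPlateauProfile <- function(n_cells = 1000, n_ambient = 100000) {
    umi <- c(round(seq(10000, 9900, length.out = n_cells)),
             round(seq(150, 50, length.out = n_ambient)))
    names(umi) <- sprintf("BC%06d", seq_along(umi))
    barcodeRankProfile(umi)
}

# Exact Gaussian KDE evaluated at arbitrary points (the no-grid density
# oracle used against the FFT-grid implementation).
exactKde <- function(at, data, bw) {
    vapply(at, function(x) mean(stats::dnorm(x, mean = data, sd = bw)), 0)
}
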