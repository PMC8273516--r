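test_that("size factors match the median-of-ratios definition", {
    m <- matrix(rep(c(10, 20, 30), 3), 3, 3,
                dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
    expect_equal(unname(bulkSizeFactors(m)), rep(1, 3))
    set.seed(2)
    m2 <- matrix(rpois(200, 100), 100, 2,
                 dimnames = list(sprintf("g%03d", 1:100), c("a", "b")))
    m2[, 2] <- m2[, 1] * 2L
    sf <- bulkSizeFactors(m2)
    expect_equal(unname(sf[2] / sf[1]), 2, tolerance = 1e-12)
    expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-12)
    # literal loop oracle
    m3 <- matrix(rnbinom(300, mu = 80, size = 10), 50, 6,
                 dimnames = list(sprintf("g%03d", 1:50), paste0("s", 1:6)))
    gm <- exp(rowMeans(log(m3)))
    ok <- is.finite(log(gm)) & gm > 0
    manual <- apply(m3, 2, function(col) median(col[ok] / gm[ok]))
    manual <- manual / exp(mean(log(manual)))
    expect_equal(bulkSizeFactors(m3), manual, tolerance = 1e-12)
    # all-zero row everywhere -> still fine; all genes with a zero -> error
    m4 <- m3; m4[cbind(1:50, rep_len(1:6, 50))] <- 0L
    expect_error(bulkSizeFactors(m4), "pseudo-reference")
})

test_that("size factors agree with the DESeq2 reference implementation", {
    skip_if_not_installed("DESeq2")
    set.seed(5)
    m <- matrix(rnbinom(606, mu = 150, size = 15), 101, 6,
                dimnames = list(sprintf("g%03d", 1:101), paste0("s", 1:6)))
    ref <- DESeq2::estimateSizeFactorsForMatrix(m)
    ref <- ref / exp(mean(log(ref)))
    expect_equal(bulkSizeFactors(m), ref, tolerance = 1e-10)
})

test_that("NB Wald test handles degenerate and excluded genes", {
    m <- matrix(c(rep(50L, 6), rep(c(20L, 80L), each = 3), rep(1L, 6)),
                3, 6, byrow = TRUE,
                dimnames = list(c("same", "diff", "low"), paste0("s", 1:6)))
    grp <- factor(rep(c("A", "B"), each = 3))
    res <- nbWaldTest(m, grp)
    expect_equal(res$log2_fold_change[res$gene_id == "same"], 0)
    expect_gt(res$p_value[res$gene_id == "same"], 0.99)
    expect_identical(res$enrichment_class[res$gene_id == "low"],
                     "low_count_excluded")
    expect_true(is.na(res$p_adjusted[res$gene_id == "low"]))
    expect_equal(res$fold_change, 2^res$log2_fold_change, tolerance = 1e-6)
    expect_error(nbWaldTest(m, factor(c("A", "A", "A", "A", "A", "B"))),
                 "at least 2 samples")
    expect_error(nbWaldTest(m, factor(rep("A", 6))), "two levels")
})

test_that("label swap negates fold changes and swaps classes", {
    cfg <- smallSimConfig(seed = 17)
    truth <- simulateTruth(cfg)
    m <- as.matrix(counts(simulateBulk(cfg, truth)$counts))
    g1 <- factor(rep(c("A", "B"), each = 3), levels = c("A", "B"))
    g2 <- factor(rep(c("A", "B"), each = 3), levels = c("B", "A"))
    r1 <- classifyEnrichment(nbWaldTest(m, g1))
    r2 <- classifyEnrichment(nbWaldTest(m, g2))
    expect_equal(r2$log2_fold_change, -r1$log2_fold_change,
                 tolerance = 1e-12)
    expect_equal(r2$p_value, r1$p_value, tolerance = 1e-12)
    expect_identical(r2$enrichment_class == "A_enriched",
                     r1$enrichment_class == "B_enriched")
})

test_that("BH adjustment is monotone after sorting by p-value", {
    cfg <- smallSimConfig(seed = 23)
    truth <- simulateTruth(cfg)
    res <- nbWaldTest(as.matrix(counts(simulateBulk(cfg, truth)$counts)),
                      factor(rep(c("A", "B"), each = 3)))
    tested <- res[!is.na(res$p_value), ]
    tested <- tested[order(tested$p_value), ]
    expect_true(all(diff(tested$p_adjusted) >= -1e-15))
    expect_true(all(tested$p_adjusted >= tested$p_value))
})

test_that("the null false-positive rate stays within 1%", {
    fprs <- vapply(1:3, function(s) {
        cfg <- simulationConfig(n_genes = 2000L,
                                n_specific_markers = c(FLC = 0L, ALC = 0L),
                                n_trap_low = c(FLC = 0L, ALC = 0L),
                                n_trap_no_bulk = c(FLC = 0L, ALC = 0L),
                                n_bulk_de = c(A = 0L, B = 0L),
                                n_cluster_markers = 0L, seed = s)
        truth <- simulateTruth(cfg)
        m <- as.matrix(counts(simulateBulk(cfg, truth)$counts))
        res <- nbWaldTest(m, factor(rep(c("A", "B"), each = 3)))
        mean(res$p_adjusted < 0.01, na.rm = TRUE)
    }, 0)
    expect_true(all(fprs <= 0.01))
})

test_that("planted strong effects are recovered with the right sign", {
    cfg <- smallSimConfig(seed = 31)
    truth <- simulateTruth(cfg)
    m <- as.matrix(counts(simulateBulk(cfg, truth)$counts))
    res <- nbWaldTest(m, factor(rep(c("A", "B"), each = 3)))
    planted <- truth[truth$planted_log2fc != 0, ]
    ri <- match(planted$gene_id, res$gene_id)
    hit <- res$p_adjusted[ri] < 0.01 &
        sign(res$log2_fold_change[ri]) == sign(planted$planted_log2fc)
    expect_gte(mean(hit, na.rm = TRUE), 0.9)
})

test_that("NB rejections reach the exact Mann-Whitney floor at n = 3", {
    cfg <- smallSimConfig(seed = 37)
    truth <- simulateTruth(cfg)
    m <- as.matrix(counts(simulateBulk(cfg, truth)$counts))
    sf <- bulkSizeFactors(m)
    norm <- sweep(m, 2, sf, `/`)
    res <- nbWaldTest(m, factor(rep(c("A", "B"), each = 3)))
    planted <- truth$gene_id[truth$planted_log2fc != 0]
    rej <- intersect(planted,
                     res$gene_id[!is.na(res$p_adjusted) &
                                 res$p_adjusted < 0.01])
    mw <- vapply(rej, function(g)
        wilcox.test(norm[g, 1:3], norm[g, 4:6], exact = TRUE)$p.value, 0)
    expect_gte(mean(mw <= 0.1 + 1e-12), 0.8)
})

test_that("enrichment classification applies strict cutoffs", {
    res <- data.frame(gene_id = paste0("g", 1:5),
                      base_mean = 100, log2_fold_change = 0,
                      fold_change = c(3, 1.5, 0.01, 2, 0.5),
                      p_value = 0.001,
                      p_adjusted = c(0.005, 0.005, 0.02, 0.005, 0.005),
                      enrichment_class = "not_significant",
                      stringsAsFactors = FALSE)
    out <- classifyEnrichment(res)
    expect_identical(out$enrichment_class,
                     c("B_enriched",       # padj 0.005, FC 3
                       "not_significant",  # FC between bounds
                       "not_significant",  # fails padj
                       "not_significant",  # FC exactly 2: strict
                       "not_significant")) # FC exactly 0.5: strict
})

test_that("log2FC-fold-change conversion reproduces the reference rows", {
    expect_equal(roundHalfUp(log2fcToFc(-10.022), 3), 0.001)
    expect_equal(log2fcToFc(9.798), 890.151, tolerance = 0.001)
    expect_identical(log2fcToFc(0), 1)
})

test_that("DE gene clustering separates planted expression patterns", {
    # two perfectly anti-correlated blocks split exactly at k = 2
    prof <- rbind(matrix(rep(c(1, 2, 3, 4), each = 10), 10, 4),
                  matrix(rep(c(4, 3, 2, 1), each = 10), 10, 4))
    rownames(prof) <- sprintf("g%02d", 1:20)
    colnames(prof) <- paste0("s", 1:4)
    cl <- clusterDeGenes(prof, rownames(prof), k = 2)
    expect_length(unique(cl$cluster_index[1:10]), 1)
    expect_length(unique(cl$cluster_index[11:20]), 1)
    expect_false(cl$cluster_index[1] == cl$cluster_index[11])
    # k = number of genes: singletons
    cl2 <- clusterDeGenes(prof[1:5, ] + matrix(rnorm(20, sd = 0.01), 5),
                          rownames(prof)[1:5], k = 5)
    expect_length(unique(cl2$cluster_index), 5)
    # zero-variance gene is flagged and still assigned
    prof2 <- rbind(prof, flatg = rep(2, 4))
    cl3 <- clusterDeGenes(prof2, rownames(prof2), k = 2)
    expect_true(cl3$zero_variance[cl3$gene_id == "flatg"])
    expect_false(is.na(cl3$cluster_index[cl3$gene_id == "flatg"]))
    expect_error(clusterDeGenes(prof, rownames(prof), k = 25), "at least k")
})

test_that("planted mean-profiles are recovered with high adjusted Rand index", {
    skip_if_not_installed("mclust")
    aris <- vapply(1:5, function(s) {
        set.seed(s)
        centers <- matrix(c(5, 0, 0, 0, 5, 0, 0, 0, 5), 3, 3, byrow = TRUE)
        truth_lab <- rep(1:3, each = 20)
        x <- centers[truth_lab, ] + matrix(rnorm(180, sd = 0.5), 60, 3)
        rownames(x) <- sprintf("g%02d", 1:60)
        colnames(x) <- paste0("s", 1:3)
        cl <- clusterDeGenes(x, rownames(x), k = 3)
        mclust::adjustedRandIndex(cl$cluster_index, truth_lab)
    }, 0)
    expect_true(all(aris >= 0.9))
})
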