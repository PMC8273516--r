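test_that("cell normalization matches its closed form, sparse and dense", {
    m <- Matrix::sparseMatrix(i = c(1, 2, 1), j = c(1, 1, 2),
                              x = c(3, 7, 5), dims = c(2, 2))
    dimnames(m) <- list(c("g1", "g2"), c("c1", "c2"))
    n <- normalizeCells(m)
    expect_equal(n["g1", "c1"], log1p(10000 * 3 / 10))
    expect_equal(n["g2", "c2"], 0)                     # zero stays zero
    # count equal to the cell total
    expect_equal(n["g1", "c2"], log(10001))
    expect_equal(as.matrix(n), normalizeCells(as.matrix(m)))
    set.seed(6)
    m2 <- matrix(rpois(200, 2), 20, 10,
                 dimnames = list(sprintf("g%02d", 1:20),
                                 sprintf("c%02d", 1:10)))
    m2[, 1] <- pmax(m2[, 1], 1L)
    n2 <- normalizeCells(m2, scale = 500)
    for (j in 1:10) for (i in 1:20)
        expect_equal(n2[i, j], log1p(500 * m2[i, j] / sum(m2[, j])),
                     tolerance = 1e-12)
    bad <- m2; bad[, 3] <- 0L
    expect_error(normalizeCells(bad, 500), "zero total counts: c03")
})

test_that("rank-sum p approximates the exact enumeration at n = 3 + 3", {
    # exact two-sided p for fully separated groups, by enumeration of all
    # 20 assignments of ranks {1..6} into two triples
    vals <- 1:6
    combs <- combn(6, 3)
    stats <- apply(combs, 2, function(ix) sum(rank(vals)[ix]) - 6)  # U_in
    obs <- 0                                 # {4,5,6} in, {1,2,3} out -> U=0
    exact_p <- mean(abs(stats - 4.5) >= abs(obs - 4.5)) # symmetric around 4.5
    expect_equal(exact_p, 0.1)
    norm <- matrix(c(4, 5, 6, 1, 2, 3), 1, 6,
                   dimnames = list("g1", paste0("c", 1:6)))
    ms <- wilcoxonMarkerTest(norm, paste0("c", 1:3), paste0("c", 4:6),
                             min_pct = 0, logfc_prefilter = -Inf)
    expect_lt(abs(ms$p_value - exact_p), 0.05)
    expect_lt(abs(ms$p_value -
                  wilcox.test(c(4, 5, 6), c(1, 2, 3),
                              exact = TRUE)$p.value), 0.05)
})

test_that("detection fractions equal brute-force nonzero counts", {
    norm <- rbind(g1 = c(0, 1, 2, 0, 0, 3, 0),
                  g2 = c(1, 1, 1, 1, 2, 2, 2))
    colnames(norm) <- paste0("c", 1:7)
    ms <- wilcoxonMarkerTest(norm, paste0("c", 1:4), paste0("c", 5:7),
                             min_pct = 0, logfc_prefilter = -Inf,
                             positive_only = FALSE)
    expect_equal(ms$pct_1[ms$gene_id == "g1"], 0.5)   # (0,1,2,0)
    expect_equal(ms$pct_2[ms$gene_id == "g1"], 1 / 3)
    expect_equal(ms$pct_1[ms$gene_id == "g2"], 1)
})

test_that("marker statistics validate their cell sets", {
    norm <- matrix(1, 2, 6, dimnames = list(c("g1", "g2"), paste0("c", 1:6)))
    expect_error(wilcoxonMarkerTest(norm, paste0("c", 1:3),
                                    paste0("c", 3:6)), "overlap")
    expect_error(wilcoxonMarkerTest(norm, paste0("c", 1:2),
                                    paste0("c", 3:6)), "at least 3")
})

test_that("avg_logfc is antisymmetric and ranks are transform-invariant", {
    set.seed(12)
    norm <- matrix(abs(rnorm(120)), 10, 12,
                   dimnames = list(sprintf("g%02d", 1:10),
                                   sprintf("c%02d", 1:12)))
    cin <- sprintf("c%02d", 1:6); cout <- sprintf("c%02d", 7:12)
    a <- wilcoxonMarkerTest(norm, cin, cout, min_pct = 0,
                            logfc_prefilter = -Inf, positive_only = FALSE)
    b <- wilcoxonMarkerTest(norm, cout, cin, min_pct = 0,
                            logfc_prefilter = -Inf, positive_only = FALSE)
    expect_equal(a$avg_logfc, -b$avg_logfc, tolerance = 1e-12)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
    # strictly monotone transform preserving zero preserves the test
    tr <- wilcoxonMarkerTest(norm^3, cin, cout, min_pct = 0,
                             logfc_prefilter = -Inf, positive_only = FALSE)
    expect_equal(tr$p_value, a$p_value, tolerance = 1e-12)
    expect_equal(tr$pct_1, a$pct_1)
})

test_that("null genes essentially never pass the marker criteria", {
    rates <- vapply(1:5, function(s) {
        set.seed(s)
        m <- matrix(rpois(200 * 60, 1.5), 200, 60,
                    dimnames = list(sprintf("g%03d", 1:200),
                                    sprintf("c%02d", 1:60)))
        m[1, ] <- pmax(m[1, ], 1L)    # keep cell totals positive
        norm <- normalizeCells(m)
        ms <- wilcoxonMarkerTest(norm, colnames(m)[1:30], colnames(m)[31:60],
                                 min_pct = 0, logfc_prefilter = -Inf,
                                 positive_only = FALSE)
        mean(ms$p_adjusted < 0.01)
    }, 0)
    expect_true(all(rates <= 0.01))
})

test_that("pairwise markers pass only in the planted orientation", {
    cfg <- smallSimConfig(seed = 41)
    truth <- simulateTruth(cfg)
    sc <- simulateSingleCell(cfg, truth)
    norm <- normalizeCells(sc$counts)
    pw <- pairwiseMarkers(norm, sc$labels, "FLC", "ALC")
    flc_markers <- truth$gene_id[truth$role == "specific_marker" &
                                 truth$target == "FLC"]
    for (g in flc_markers) {
        expect_true(pw$passes_marker_criteria[pw$gene_id == g &
                                              pw$group_in == "FLC"])
        expect_false(pw$passes_marker_criteria[pw$gene_id == g &
                                               pw$group_in == "ALC"])
    }
    expect_error(pairwiseMarkers(norm, sc$labels, "FLC", "NoSuch"),
                 "cluster absent")
})

test_that("pct criteria are strict at their boundaries", {
    # 20 in-cells with 9 nonzero (pct_1 = 0.45); 20 out-cells with 5
    # nonzero (pct_2 = 0.25): both must fail the strict inequalities
    set.seed(2)
    gene45 <- c(rep(5, 9), rep(0, 11))
    gene25out <- c(rep(5, 20), rep(4, 5), rep(0, 15))
    norm <- rbind(g45 = c(gene45, rep(0.01, 20)),
                  g25 = gene25out)
    colnames(norm) <- sprintf("c%02d", 1:40)
    cin <- sprintf("c%02d", 1:20); cout <- sprintf("c%02d", 21:40)
    ms <- wilcoxonMarkerTest(norm, cin, cout, min_pct = 0,
                             logfc_prefilter = -Inf)
    expect_equal(ms$pct_1[ms$gene_id == "g45"], 0.45)
    expect_false(ms$passes_marker_criteria[ms$gene_id == "g45"])
    expect_equal(ms$pct_2[ms$gene_id == "g25"], 0.25)
    expect_false(ms$passes_marker_criteria[ms$gene_id == "g25"])
})

test_that("one-vs-rest reduces to pairwise with two clusters", {
    cfg <- smallSimConfig(seed = 43,
                          cell_counts_per_cluster = c(FLC = 40L, ALC = 40L,
                                                      FetalSertoli = 3L,
                                                      Interstitial = 3L,
                                                      AdultSertoli = 3L,
                                                      Germ = 3L))
    truth <- simulateTruth(cfg)
    sc <- simulateSingleCell(cfg, truth)
    keep <- sc$labels$cluster %in% c("FLC", "ALC")
    labels2 <- sc$labels[keep, ]
    norm <- normalizeCells(counts(sc$counts)[, labels2$cell_id])
    ovr <- oneVsRestMarkers(norm, labels2)
    pw <- pairwiseMarkers(norm, labels2, "FLC", "ALC")
    for (cl in c("FLC", "ALC")) {
        o <- ovr[ovr$cluster == cl, ]
        p <- pw[pw$group_in == cl, ]
        expect_equal(o$p_value, p$p_value, tolerance = 1e-12)
        expect_equal(o$avg_logfc, p$avg_logfc, tolerance = 1e-12)
        expect_identical(o$passes_marker_criteria,
                         p$passes_marker_criteria)
    }
})

test_that("one-vs-rest skips tiny clusters and bounds shared markers", {
    cfg <- smallSimConfig(seed = 47)
    truth <- simulateTruth(cfg)
    sc <- simulateSingleCell(cfg, truth)
    norm <- normalizeCells(sc$counts)
    labels <- sc$labels
    labels$cluster[labels$cell_id == labels$cell_id[1]] <- "Singleton"
    expect_warning(oneVsRestMarkers(norm, labels), "fewer than 3")

    # a gene broadly expressed in several clusters fails pct_2 < 0.25 in
    # each of them, because the others also express it broadly
    m <- counts(sc$counts)
    shared <- "sharedg"
    mrow <- Matrix::Matrix(0, 1, ncol(m), sparse = TRUE,
                           dimnames = list(shared, colnames(m)))
    inc <- sc$labels$cluster %in% c("FLC", "ALC", "AdultSertoli")
    set.seed(1)
    mrow[1, inc] <- rpois(sum(inc), 5) + 1
    m2 <- rbind(m, mrow)
    norm2 <- normalizeCells(m2)
    ovr <- oneVsRestMarkers(norm2, sc$labels)
    sh <- ovr[ovr$gene_id == shared &
              ovr$cluster %in% c("FLC", "ALC", "AdultSertoli"), ]
    expect_true(all(sh$pct_2 > 0.25))
    expect_false(any(sh$passes_marker_criteria))

    # planted cluster-exclusive markers pass for their own cluster only
    markers <- truth[truth$role == "sc_marker", ]
    for (i in seq_len(nrow(markers))) {
        own <- ovr$passes_marker_criteria[ovr$gene_id ==
                                          markers$gene_id[i]]
        names(own) <- ovr$cluster[ovr$gene_id == markers$gene_id[i]]
        expect_true(own[[markers$target[i]]])
        expect_false(any(own[names(own) != markers$target[i]]))
    }
})
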