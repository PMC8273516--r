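#' @importFrom stats density median
NULL

#' Build a ranked barcode profile
#'
#' @param total_umi named non-negative integer vector of per-barcode UMI
#'   totals (names are barcodes; generated if absent).
#' @return data.frame with `barcode`, `total_umi`, `rank` (1 = largest
#'   total), sorted by rank; ties in UMI are broken by barcode lexicographic
#'   order so the ranking is a deterministic permutation.
#' @export
barcodeRankProfile <- function(total_umi) {
    if (any(!is.finite(total_umi)) || any(total_umi < 0))
        stop("total_umi must be non-negative and finite")
    if (any(total_umi != round(total_umi)))
        stop("total_umi must be integer-valued")
    bc <- names(total_umi)
    if (is.null(bc)) bc <- sprintf("BC%07d", seq_along(total_umi))
    ord <- order(-total_umi, bc)
    data.frame(barcode = bc[ord], total_umi = as.numeric(total_umi[ord]),
               rank = seq_along(total_umi), stringsAsFactors = FALSE)
}

#' Knee and inflection of the ranked barcode curve
#'
#' Works on the log10(total UMI) versus log10(rank) curve after collapsing
#' tied UMI values to one point (at the largest rank carrying that value).
#' Because the collapsed abscissae are grossly uneven — log-rank spacings
#' shrink toward both ends of the curve — the curve is first resampled by
#' linear interpolation onto an equally spaced log-rank grid, then the
#' ordinate is smoothed with a centered moving average. The knee is the
#' grid point of minimum signed curvature y''/(1+y'^2)^(3/2) (most
#' negative); the inflection is the steepest descent (minimum first
#' derivative) at a rank greater than the knee's. Both are reported as UMI
#' values (back-transformed from the smoothed curve).
#'
#' @param profile a [barcodeRankProfile()].
#' @param smooth_frac moving-average window as a fraction of the resampled
#'   grid (default 5%; at least 3 points).
#' @param grid_size resampling grid size, default 512.
#' @param min_curvature required magnitude of the (negative) curvature at
#'   the knee; flatter curves (e.g. a straight power law with no shoulder)
#'   raise "no knee detectable". Default 1; real knees on droplet data sit
#'   an order of magnitude beyond this.
#' @param exclude_below barcodes with totals below this are left out of the
#'   landmark search (default 100), the usual droplet-QC guard against the
#'   deep ambient tail.
#' @return list with `knee_umi` and `inflection_umi` (UMI values).
#' @export
findKneeInflection <- function(profile, smooth_frac = 0.05,
                               grid_size = 512, min_curvature = 1,
                               exclude_below = 100) {
    stopifnot(is.data.frame(profile),
              all(c("total_umi", "rank") %in% names(profile)))
    if (nrow(profile) < 100)
        stop("need at least 100 barcodes")
    umi <- profile$total_umi[order(profile$rank)]
    umi <- umi[umi > 0]
    vals <- unique(umi)                      # descending
    if (length(vals) < 2)
        stop("no knee detectable: fewer than 2 distinct UMI values")
    last_rank <- cumsum(tabulate(match(umi, vals)))
    keep <- vals >= exclude_below
    if (sum(keep) >= 5) {
        vals <- vals[keep]
        last_rank <- last_rank[keep]
    }
    x0 <- log10(last_rank)
    y0 <- log10(vals)
    if (length(vals) < 5)
        stop("no knee detectable: too few distinct UMI values")
    n <- as.integer(grid_size)
    xg <- seq(x0[1], x0[length(x0)], length.out = n)
    yg <- stats::approx(x0, y0, xout = xg, ties = min)$y
    w <- max(3L, round(smooth_frac * n))
    if (w %% 2 == 0) w <- w + 1L
    ys <- movingAverage(yg, w)
    d1 <- finiteDiff(xg, ys)
    d2 <- finiteDiff(xg, d1)
    curv <- d2 / (1 + d1^2)^1.5
    # the asymmetric smoothing window biases the curve near both ends;
    # keep the landmark search away from that margin
    interior <- seq(w + 1L, n - w)
    ki <- interior[which.min(curv[interior])]
    if (!is.finite(curv[ki]) || curv[ki] > -min_curvature)
        stop("no knee detectable: curve has no shoulder")
    after <- seq_len(n) > ki
    if (!any(after)) stop("no knee detectable: knee at curve end")
    ii <- which(after)[which.min(d1[after])]
    list(knee_umi = 10^ys[ki], inflection_umi = 10^ys[ii])
}

movingAverage <- function(y, w) {
    half <- (w - 1L) %/% 2L
    n <- length(y)
    cs <- cumsum(c(0, y))
    lo <- pmax(1L, seq_len(n) - half)
    hi <- pmin(n, seq_len(n) + half)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Central finite differences with one-sided ends, on possibly uneven x.
finiteDiff <- function(x, y) {
    n <- length(x)
    d <- numeric(n)
    d[1] <- (y[2] - y[1]) / (x[2] - x[1])
    d[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    if (n > 2) {
        i <- 2:(n - 1)
        d[i] <- (y[i + 1] - y[i - 1]) / (x[i + 1] - x[i - 1])
    }
    d
}

#' Density-minimum cell-calling threshold
#'
#' Gaussian kernel density of the raw per-barcode UMI totals evaluated on an
#' equally spaced grid spanning `[0, max UMI]`; among grid-local minima
#' (strictly smaller than both neighbors) whose UMI value lies within
#' `[inflection_umi, knee_umi]`, the one with smallest density (ties: the
#' smaller UMI) becomes the threshold. Barcodes with a total strictly above
#' the threshold are called as cells. If no local minimum falls in the
#' interval, the geometric mean of knee and inflection is used and flagged.
#'
#' @param profile a [barcodeRankProfile()].
#' @param knee_umi,inflection_umi landmarks from [findKneeInflection()].
#' @param bandwidth Gaussian kernel standard deviation on the raw UMI scale
#'   (default 500; the raw scale is what makes this bandwidth meaningful).
#' @param grid_points grid size (default 4096).
#' @return a `CallingResult` list: `knee_umi`, `inflection_umi`,
#'   `threshold_umi`, `called_barcodes`, `n_called`, `density_grid`
#'   (data.frame `umi`/`density`), `fallback` flag.
#' @export
densityThreshold <- function(profile, knee_umi, inflection_umi,
                             bandwidth = 500, grid_points = 4096) {
    if (!(knee_umi > inflection_umi))
        stop("knee_umi must exceed inflection_umi")
    umi <- profile$total_umi
    d <- density(umi, bw = bandwidth, n = grid_points, from = 0,
                 to = max(umi))
    y <- d$y
    n <- length(y)
    lm_idx <- which(y[2:(n - 1)] < y[1:(n - 2)] &
                    y[2:(n - 1)] < y[3:n]) + 1L
    in_win <- lm_idx[d$x[lm_idx] >= inflection_umi &
                     d$x[lm_idx] <= knee_umi]
    fallback <- length(in_win) == 0L
    if (fallback) {
        threshold <- sqrt(as.numeric(knee_umi) * as.numeric(inflection_umi))
    } else {
        best <- in_win[order(y[in_win], d$x[in_win])][1]
        threshold <- d$x[best]
    }
    called <- profile$barcode[profile$total_umi > threshold]
    structure(list(knee_umi = knee_umi, inflection_umi = inflection_umi,
                   threshold_umi = threshold, called_barcodes = called,
                   n_called = length(called),
                   density_grid = data.frame(umi = d$x, density = d$y),
                   fallback = fallback),
              class = "CallingResult")
}

#' @export
print.CallingResult <- function(x, ...) {
    cat(sprintf(
        "CallingResult: knee %s, inflection %s, threshold %.1f%s -> %d cells\n",
        format(x$knee_umi), format(x$inflection_umi), x$threshold_umi,
        if (x$fallback) " (fallback: geometric mean)" else "",
        x$n_called))
    invisible(x)
}

#' Call cell-containing barcodes
#'
#' Convenience wrapper: [findKneeInflection()] then [densityThreshold()].
#'
#' @inheritParams findKneeInflection
#' @inheritParams densityThreshold
#' @return a `CallingResult` (see [densityThreshold()]).
#' @export
callCells <- function(profile, smooth_frac = 0.05, grid_size = 512,
                      min_curvature = 1, exclude_below = 100,
                      bandwidth = 500, grid_points = 4096) {
    ki <- findKneeInflection(profile, smooth_frac = smooth_frac,
                             grid_size = grid_size,
                             min_curvature = min_curvature,
                             exclude_below = exclude_below)
    densityThreshold(profile, ki$knee_umi, ki$inflection_umi,
                     bandwidth = bandwidth, grid_points = grid_points)
}
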