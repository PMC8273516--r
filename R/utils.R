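# Small shared helpers.

#' Round half away from zero
#'
#' Rounds with ties going away from zero (0.5 -> 1), the convention used for
#' the reported percentages, unlike base R's round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 0) {
    p <- 10^digits
    sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic child seed for a pipeline stage, derived from the master
# seed and the stage name so that stages draw independent streams while the
# whole run stays a pure function of one integer. Kept below 2^31 - 1.
childSeed <- function(seed, stage) {
    h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
    as.integer((as.numeric(seed) %% 65536 * 104729 + h * 7919) %% 2147483647L)
}

writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    invisible(path)
}

readTsv <- function(path, ...) {
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                      ...)
}
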