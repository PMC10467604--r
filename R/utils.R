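#' @importFrom stats pnorm pt qnorm rbinom rnbinom rnorm runif rbeta sd
#'   median quantile complete.cases fisher.test cor cor.test p.adjust
#'   setNames var dhyper rhyper qbinom qhyper rgamma rexp ave
#' @importFrom utils head
#' @importFrom data.table := .N .SD data.table fread fwrite rbindlist
#'   setnames setkey setattr setorder as.data.table
NULL

.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

clip01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

#' Rounded percentage share
#'
#' Integer-rounded percentage `100 * k / n`, the convention used in the
#' cohort summary tables (DMR direction shares, eQTM/DMR overlap shares,
#' literature concordance shares).
#'
#' @param k Numerator count.
#' @param n Denominator count.
#' @return Integer percentage; 0 when `n == 0`.
#' @export
pct_share <- function(k, n) {
  ifelse(n == 0, 0L, as.integer(round(100 * k / n)))
}

stop_if <- function(cond, ...) if (cond) stop(..., call. = FALSE)

# BED-style data.frame -> GRanges (0-based half-open input)
as_granges <- function(df) {
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  strand[!strand %in% c("+", "-")] <- "*"
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = strand
  )
}

write_tsv0 <- function(df, path, col.names = TRUE) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE,
                     col.names = col.names, eol = "\n", scipen = 50)
  invisible(path)
}
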