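#' Read a per-sample CpG cytosine report
#'
#' Parses a Bismark-style cytosine report (tab-separated:
#' chromosome, 1-based position, strand, methylated count, unmethylated
#' count) and collapses the two strands of each CpG onto the plus-strand
#' cytosine. CpG methylation is symmetric between strands, so the minus
#' strand position `p` is merged into position `p - 1` with counts summed.
#'
#' @param path Path to the report.
#' @param sample_id Sample label attached to the result.
#' @return A `data.table` with columns `chrom`, `pos` (1-based, plus
#'   strand), `meth`, `total`, sorted by (`chrom`, `pos`), with attribute
#'   `sample_id`.
#' @export
read_cpg_report <- function(path, sample_id = basename(path)) {
  empty <- file.exists(path) && file.size(path) == 0
  dt <- if (empty) data.table::data.table() else
    data.table::fread(path, header = FALSE, sep = "\t",
                      colClasses = list(character = 1, character = 3))
  if (nrow(dt) == 0) {
    warning("empty cytosine report: ", path)
    out <- data.table::data.table(chrom = character(), pos = integer(),
                                  meth = integer(), total = integer())
    data.table::setattr(out, "sample_id", sample_id)
    return(out)
  }
  stop_if(ncol(dt) < 5, "cytosine report needs >= 5 columns: ", path)
  data.table::setnames(dt, 1:5, c("chrom", "pos", "strand", "meth", "unmeth"))
  bad <- which(!dt$strand %in% c("+", "-") | is.na(dt$pos) |
                 is.na(dt$meth) | is.na(dt$unmeth))
  stop_if(length(bad) > 0, "malformed cytosine report line ", bad[1],
          " in ", path)
  stop_if(any(dt$meth < 0) || any(dt$unmeth < 0),
          "negative counts in ", path)
  dt[, `:=`(pos = as.integer(ifelse(strand == "-", pos - 1L, pos)),
            total = meth + unmeth)]
  out <- dt[, .(meth = sum(meth), total = sum(total)), by = .(chrom, pos)]
  data.table::setkey(out, chrom, pos)
  data.table::setattr(out, "sample_id", sample_id)
  out[]
}

#' Assemble per-sample CpG reports into a cohort count object
#'
#' Takes the union of CpG positions across samples; a position absent
#' from a sample's report gets zero coverage there (it is then masked by
#' the minimum-coverage filter).
#'
#' @param reports Named list of `data.table`s from [read_cpg_report()].
#' @return A `cpg_counts` object: list with `sites` (data.table `chrom`,
#'   `pos`), `meth` and `total` (sites x samples integer matrices) and
#'   `samples`.
#' @export
cpg_matrix <- function(reports) {
  stop_if(is.null(names(reports)) || any(names(reports) == ""),
          "reports must be a named list (names = sample ids)")
  samples <- names(reports)
  all_sites <- unique(data.table::rbindlist(
    lapply(reports, function(r) r[, .(chrom, pos)])))
  data.table::setkey(all_sites, chrom, pos)
  n <- nrow(all_sites)
  meth <- matrix(0L, n, length(samples), dimnames = list(NULL, samples))
  total <- meth
  for (s in samples) {
    r <- reports[[s]]
    idx <- all_sites[r[, .(chrom, pos)], which = TRUE]
    meth[idx, s] <- r$meth
    total[idx, s] <- r$total
  }
  structure(list(sites = all_sites, meth = meth, total = total,
                 samples = samples),
            class = "cpg_counts")
}

#' Site filter configuration
#'
#' @param min_cov,max_cov Inclusive per-sample coverage bounds; sites
#'   outside `[min_cov, max_cov]` are masked (set missing) for that
#'   sample only.
#' @param snp_blacklist `data.frame(chrom, pos)` of positions confounded
#'   by C>T / G>A variants, dropped for all samples. `NULL` for none.
#' @param excluded_chroms Chromosomes dropped outright (sex chromosomes
#'   by default, to avoid X-inactivation-driven artefacts).
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_cov = 10L, max_cov = 500L,
                          snp_blacklist = NULL,
                          excluded_chroms = c("chrX", "chrY")) {
  stop_if(min_cov > max_cov, "min_cov must be <= max_cov")
  structure(list(min_cov = as.integer(min_cov),
                 max_cov = as.integer(max_cov),
                 snp_blacklist = snp_blacklist,
                 excluded_chroms = excluded_chroms),
            class = "filter_config")
}

#' Apply site filters to a CpG count object
#'
#' Coverage bounds mask per sample (the site stays, its counts become
#' `NA` for that sample); blacklist positions and excluded chromosomes
#' drop the site for all samples.
#'
#' @param x A `cpg_counts` object.
#' @param cfg A [filter_config()].
#' @return Filtered `cpg_counts`; masked entries are `NA` in both count
#'   matrices.
#' @export
filter_sites <- function(x, cfg = filter_config()) {
  stopifnot(inherits(x, "cpg_counts"))
  keep <- !(x$sites$chrom %in% cfg$excluded_chroms)
  if (!is.null(cfg$snp_blacklist) && nrow(cfg$snp_blacklist) > 0) {
    bl <- paste(cfg$snp_blacklist$chrom, cfg$snp_blacklist$pos)
    keep <- keep & !(paste(x$sites$chrom, x$sites$pos) %in% bl)
  }
  sites <- x$sites[keep]
  meth <- x$meth[keep, , drop = FALSE]
  total <- x$total[keep, , drop = FALSE]
  mask <- total < cfg$min_cov | total > cfg$max_cov
  meth[mask] <- NA_integer_
  total[mask] <- NA_integer_
  structure(list(sites = sites, meth = meth, total = total,
                 samples = x$samples),
            class = "cpg_counts")
}
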