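#' Promoter and gene-body intervals from gene models
#'
#' Promoters are the 1,000 bp immediately upstream of the TSS,
#' strand-aware and abutting it; the gene body is the transcribed span
#' itself. All intervals 0-based half-open.
#'
#' @param genes Gene models (`gene`, `chrom`, `strand`, `start`, `end`,
#'   `tss`; `tss` 0-based).
#' @param promoter_bp Promoter width (default 1000).
#' @return List of two `data.table`s, `promoter` and `body`.
#' @export
gene_regions <- function(genes, promoter_bp = 1000L) {
  genes <- data.table::as.data.table(genes)
  promoter <- genes[, .(
    gene, chrom,
    start = ifelse(strand == "+", pmax(0L, tss - promoter_bp), tss + 1L),
    end = ifelse(strand == "+", tss, tss + 1L + promoter_bp))]
  body <- genes[, .(gene, chrom, start, end)]
  list(promoter = promoter, body = body)
}

#' Count DMRs per gene region, split by direction
#'
#' A DMR is assigned to every gene whose region it overlaps by at
#' least 1 bp (shared assignment for overlapping genes).
#'
#' @param dmrs DMR table ([test_tiles()]); only rows with `is_dmr`
#'   count.
#' @param genes Gene models.
#' @param region `"promoter"` or `"body"`.
#' @param promoter_bp Promoter width.
#' @return `data.table(gene, n_hyper, n_hypo)` covering every gene.
#' @export
count_gene_dmrs <- function(dmrs, genes, region = c("body", "promoter"),
                            promoter_bp = 1000L) {
  region <- match.arg(region)
  reg <- gene_regions(genes, promoter_bp)[[region]]
  dmrs <- data.table::as.data.table(dmrs)[is_dmr == TRUE]
  out <- data.table::data.table(gene = reg$gene, n_hyper = 0L,
                                n_hypo = 0L)
  if (nrow(dmrs) > 0) {
    hits <- GenomicRanges::findOverlaps(as_granges(reg), as_granges(dmrs),
                                        minoverlap = 1L,
                                        ignore.strand = TRUE)
    if (length(hits) > 0) {
      tab <- data.table::data.table(
        gene = reg$gene[S4Vectors::queryHits(hits)],
        direction = dmrs$direction[S4Vectors::subjectHits(hits)])
      cnt <- tab[, .(n = .N), by = .(gene, direction)]
      hy <- cnt[direction == "hyper"]
      ho <- cnt[direction == "hypo"]
      out[match(hy$gene, gene), n_hyper := hy$n]
      out[match(ho$gene, gene), n_hypo := ho$n]
    }
  }
  out[]
}

#' Call a gene's methylation direction from DMR counts
#'
#' Direct comparison of hyper- versus hypomethylated DMR counts across
#' the gene body: more hyper than hypo gives `hyper`, the reverse
#' `hypo`, equal non-zero counts `tied`, and no DMR at all `none`.
#'
#' @param counts `data.frame(gene, n_hyper, n_hypo)`.
#' @param contrast Contrast label carried through.
#' @return `data.table(gene, contrast, n_hyper, n_hypo, direction)`.
#' @export
call_direction <- function(counts, contrast = "") {
  counts <- data.table::as.data.table(counts)
  counts[, direction := data.table::fcase(
    n_hyper > n_hypo, "hyper",
    n_hypo > n_hyper, "hypo",
    n_hyper == 0L & n_hypo == 0L, "none",
    default = "tied")]
  counts[, contrast := contrast]
  counts[]
}

#' Concordance of direction calls with a literature gene table
#'
#' Classifies each literature gene (reported hyper/hypo in the
#' HPV-positive disease) against the cohort's direction calls in the
#' IMU-vs-reference and KRT-vs-reference contrasts: `both` (both
#' subtypes match the reported direction), `imu_only`, `krt_only`,
#' `discordant` (both subtype calls oppose the report), `no_dmr`
#' (neither subtype has any DMR in the gene), `mixed` otherwise, and
#' `unmapped` when the gene is absent from the calls.
#'
#' @param calls_imu,calls_krt [call_direction()] tables for the two
#'   subtype-vs-reference contrasts.
#' @param literature `data.frame(gene, direction)` with reported
#'   direction (`hyper`/`hypo`).
#' @return List: `genes` (per-gene class), `summary` (per reported
#'   direction: class counts and integer percentages among retained
#'   genes, retained = not discordant and mapped).
#' @export
literature_concordance <- function(calls_imu, calls_krt, literature) {
  lit <- data.table::as.data.table(literature)
  di <- calls_imu$direction[match(lit$gene, calls_imu$gene)]
  dk <- calls_krt$direction[match(lit$gene, calls_krt$gene)]
  match_i <- !is.na(di) & di == lit$direction
  match_k <- !is.na(dk) & dk == lit$direction
  opp <- function(d) ifelse(d == "hyper", "hypo", "hyper")
  conf_i <- !is.na(di) & di == opp(lit$direction)
  conf_k <- !is.na(dk) & dk == opp(lit$direction)
  cls <- data.table::fcase(
    is.na(di) & is.na(dk), "unmapped",
    match_i & match_k, "both",
    match_i & !match_k, "imu_only",
    match_k & !match_i, "krt_only",
    conf_i & conf_k, "discordant",
    di == "none" & dk == "none", "no_dmr",
    default = "mixed")
  genes <- data.table::data.table(lit, dir_imu = di, dir_krt = dk,
                                  class = cls)
  summ <- genes[class != "unmapped",
                .(n = .N,
                  n_retained = sum(class != "discordant"),
                  n_both = sum(class == "both"),
                  n_imu_only = sum(class == "imu_only"),
                  n_krt_only = sum(class == "krt_only"),
                  n_no_dmr = sum(class == "no_dmr")),
                by = .(direction)]
  summ[, imu_only_pct := pct_share(n_imu_only, n_retained)]
  list(genes = genes[], summary = summ[])
}

#' Cross-tabulate site-level methylation directions of two cohorts
#'
#' Joins two direction tables on coordinates and counts concordant
#' and reversed hyper/hypo combinations; reversed sites (opposite
#' directions) are returned for subcluster inspection.
#'
#' @param calls_a,calls_b `data.frame(chrom, start, end, direction)`
#'   with `direction` in hyper/hypo.
#' @return List: `table` (2x2 counts, rows = cohort A), `n_shared`,
#'   `reversed` (coordinate table), `reversed_frac`.
#' @export
direction_crosstab <- function(calls_a, calls_b) {
  a <- data.table::as.data.table(calls_a)
  b <- data.table::as.data.table(calls_b)
  m <- merge(a, b, by = c("chrom", "start", "end"),
             suffixes = c("_a", "_b"))
  stop_if(nrow(m) == 0, "no shared sites between the two cohorts")
  tab <- table(factor(m$direction_a, c("hyper", "hypo")),
               factor(m$direction_b, c("hyper", "hypo")),
               dnn = c("cohort_a", "cohort_b"))
  rev <- m[direction_a != direction_b]
  list(table = tab, n_shared = nrow(m), reversed = rev[],
       reversed_frac = nrow(rev) / nrow(m))
}
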