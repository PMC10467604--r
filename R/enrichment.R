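#' Annotate regions against genomic classes
#'
#' Membership by >= 1 bp overlap (half-open intervals); a region may
#' belong to several classes; a chromosome absent from a class simply
#' yields non-membership.
#'
#' @param regions `data.frame(chrom, start, end)`, 0-based half-open.
#' @param classes Named list of BED-like `data.frame`s.
#' @return Logical matrix regions x classes.
#' @export
annotate_regions <- function(regions, classes) {
  gr <- as_granges(regions)
  out <- matrix(FALSE, nrow(regions), length(classes),
                dimnames = list(NULL, names(classes)))
  for (nm in names(classes)) {
    cl <- classes[[nm]]
    if (nrow(cl) == 0) next
    hits <- GenomicRanges::countOverlaps(gr, as_granges(cl),
                                         minoverlap = 1L,
                                         ignore.strand = TRUE)
    out[, nm] <- hits > 0
  }
  out
}

#' Random regions matched in number and width
#'
#' Draws as many regions as the input with the same multiset of widths
#' (widths permuted, not resampled), placed uniformly over the allowed
#' genome; chromosomes are chosen with probability proportional to
#' length. Regions may overlap each other. Reproducible under `seed`.
#'
#' @param regions Input regions (`chrom`, `start`, `end`).
#' @param chrom_sizes Named chromosome lengths.
#' @param seed Integer seed.
#' @param excluded_chroms Chromosomes never used for placement.
#' @return `data.frame(chrom, start, end)` of random regions.
#' @export
random_matched_regions <- function(regions, chrom_sizes, seed = 1L,
                                   excluded_chroms = c("chrX", "chrY")) {
  set.seed(seed)
  sizes <- chrom_sizes[!names(chrom_sizes) %in% excluded_chroms]
  stop_if(length(sizes) == 0, "no chromosome left after exclusions")
  widths <- sample(regions$end - regions$start)
  n <- length(widths)
  chrom <- character(n); start <- integer(n)
  for (i in seq_len(n)) {
    repeat {
      ch <- sample(names(sizes), 1, prob = sizes)
      if (widths[i] <= sizes[[ch]]) break
      warning("region width ", widths[i], " exceeds chromosome ", ch,
              "; resampling placement")
    }
    chrom[i] <- ch
    start[i] <- as.integer(floor(runif(1, 0, sizes[[ch]] - widths[i] + 1)))
  }
  data.frame(chrom = chrom, start = start, end = start + widths)
}

#' Fisher enrichment of region classes versus random regions
#'
#' Per class, a 2x2 table of in/out-of-class counts for the observed
#' (e.g. DMR) and random region sets, two-sided Fisher exact test, BH
#' correction across classes, and an odds ratio (cross-product, with
#' Haldane 0.5 correction when any cell is zero). A class is flagged
#' enriched when FDR < `fdr_cut` and OR > `or_cut`.
#'
#' @param dmr_membership,rand_membership Logical membership matrices
#'   over the same classes ([annotate_regions()]).
#' @param fdr_cut,or_cut Enrichment flag thresholds (0.05 and 1.5).
#' @return `data.frame` with one row per class: counts, `odds_ratio`,
#'   `p`, `fdr`, `enriched`, `degenerate`.
#' @export
fisher_enrichment <- function(dmr_membership, rand_membership,
                              fdr_cut = 0.05, or_cut = 1.5) {
  stop_if(!identical(colnames(dmr_membership), colnames(rand_membership)),
          "membership tables must cover the same classes")
  classes <- colnames(dmr_membership)
  rows <- lapply(classes, function(cl) {
    a <- sum(dmr_membership[, cl]); b <- nrow(dmr_membership) - a
    c_ <- sum(rand_membership[, cl]); d <- nrow(rand_membership) - c_
    degenerate <- (a + c_) == 0
    p <- if (degenerate) 1 else
      stats::fisher.test(matrix(c(a, b, c_, d), 2, byrow = TRUE))$p.value
    h <- if (any(c(a, b, c_, d) == 0)) 0.5 else 0
    or <- ((a + h) * (d + h)) / ((b + h) * (c_ + h))
    data.frame(class = cl, n_dmr_in = a, n_dmr_out = b,
               n_rand_in = c_, n_rand_out = d,
               odds_ratio = or, p = p, degenerate = degenerate)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$enriched <- out$fdr < fdr_cut & out$odds_ratio > or_cut
  out
}
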