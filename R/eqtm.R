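#' Filter tiles for the cis-eQTM scan
#'
#' Three outlier-robust conditions, applied jointly: the tile is
#' covered in at least `min_sample_frac` of the samples (ceiling); the
#' coefficient of variation of its methylation fractions exceeds the
#' empirical `cv_quantile` of the CV distribution of coverage-eligible
#' tiles (removing near-constant tiles); and the number of fully
#' unmethylated samples stays below `max_zero_frac` of the cohort
#' (removing tiles whose variation is carried by one or two non-zero
#' samples).
#'
#' @param x A `meth_tiles` object.
#' @param min_sample_frac Coverage fraction (default 0.8).
#' @param cv_quantile Lower CV quantile cut (default 0.05).
#' @param max_zero_frac Maximum fully-unmethylated sample fraction
#'   (default 33/36, matching a 36-sample cohort rule of < 33).
#' @return Logical vector over tiles; attribute `cv_threshold`.
#' @export
filter_eqtm_tiles <- function(x, min_sample_frac = 0.8,
                              cv_quantile = 0.05,
                              max_zero_frac = 33 / 36) {
  stopifnot(inherits(x, "meth_tiles"))
  P <- meth_fraction(x)
  ns <- length(x$samples)
  covered <- rowSums(!is.na(P))
  cov_ok <- covered >= ceiling(min_sample_frac * ns)
  mu <- rowMeans(P, na.rm = TRUE)
  s <- apply(P, 1, stats::sd, na.rm = TRUE)
  cv <- ifelse(mu > 0, s / mu, 0)
  thr <- stats::quantile(cv[cov_ok], cv_quantile, na.rm = TRUE,
                         names = FALSE)
  n_zero <- rowSums(P == 0, na.rm = TRUE)
  ok <- cov_ok & cv > thr & n_zero < ceiling(max_zero_frac * ns)
  stop_if(!any(ok), "all tiles removed by the eQTM filters")
  attr(ok, "cv_threshold") <- thr
  ok
}

#' Candidate cis (tile, gene) pairs
#'
#' A pair is cis when the distance from the tile midpoint to the
#' gene's TSS is at most `max_dist` (inclusive) on the same
#' chromosome. The signed distance is negative upstream of the TSS
#' relative to gene strand.
#'
#' @param x A `meth_tiles` object.
#' @param genes Gene models (`gene`, `chrom`, `strand`, `tss`; `tss`
#'   0-based).
#' @param max_dist Cis window, bp (default 1e6).
#' @return `data.table(tile_idx, gene, tss_distance_bp)`.
#' @export
cis_pairs <- function(x, genes, max_dist = 1e6) {
  stopifnot(inherits(x, "meth_tiles"))
  mids <- x$tiles$start + (x$tiles$end - x$tiles$start) / 2
  skipped <- sum(is.na(genes$tss))
  if (skipped > 0) message(skipped, " gene(s) without TSS skipped")
  genes <- genes[!is.na(genes$tss), ]
  rows <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    sel <- which(x$tiles$chrom == genes$chrom[i] &
                   abs(mids - genes$tss[i]) <= max_dist)
    if (length(sel) == 0) next
    d <- mids[sel] - genes$tss[i]
    if (genes$strand[i] == "-") d <- -d
    rows[[i]] <- data.table::data.table(tile_idx = sel,
                                        gene = genes$gene[i],
                                        tss_distance_bp = d)
  }
  out <- data.table::rbindlist(rows)
  if (nrow(out) == 0)
    out <- data.table::data.table(tile_idx = integer(), gene = character(),
                                  tss_distance_bp = numeric())
  out
}

#' Fit the cis-eQTM linear models
#'
#' Per candidate pair, ordinary least squares of expression on tile
#' methylation plus covariates (`expression ~ methylation + sex + age +
#' stage + smoking` in the default configuration), t-test on the
#' methylation coefficient, BH correction pooled across all candidate
#' pairs.
#'
#' @param pairs Output of [cis_pairs()].
#' @param x A `meth_tiles` object.
#' @param expression Genes x samples matrix (log2-CPM).
#' @param covariates Numeric covariate matrix over samples (may be
#'   `NULL`), e.g. `group_design()$covariates`.
#' @param fdr_cut Significance rule on BH-adjusted p (default 0.1).
#' @param min_n Minimum complete samples per pair.
#' @return `data.table`: pair columns plus `tile_id`, `slope`, `p`,
#'   `fdr`, `sign`, `significant`, `n_used`, `skipped` (rank-deficient
#'   or under-covered pairs are kept with `skipped = TRUE`, `NA`
#'   statistics).
#' @export
fit_eqtm <- function(pairs, x, expression, covariates = NULL,
                     fdr_cut = 0.1, min_n = 10L) {
  P <- meth_fraction(x)
  samples <- x$samples
  stop_if(!all(samples %in% colnames(expression)),
          "expression matrix lacks some samples")
  E <- expression[, samples, drop = FALSE]
  Xc <- if (!is.null(covariates)) covariates[samples, , drop = FALSE]
  n_pair <- nrow(pairs)
  slope <- rep(NA_real_, n_pair); pval <- rep(NA_real_, n_pair)
  n_used <- integer(n_pair); skipped <- rep(FALSE, n_pair)
  gene_idx <- match(pairs$gene, rownames(E))
  for (i in seq_len(n_pair)) {
    m <- P[pairs$tile_idx[i], ]
    y <- E[gene_idx[i], ]
    X <- cbind(intercept = 1, meth = m, Xc)
    use <- stats::complete.cases(X) & !is.na(y)
    n_used[i] <- sum(use)
    if (n_used[i] < max(min_n, ncol(X) + 1)) { skipped[i] <- TRUE; next }
    Xu <- X[use, , drop = FALSE]
    qx <- qr(Xu)
    if (qx$rank < ncol(Xu)) { skipped[i] <- TRUE; next }
    beta <- qr.coef(qx, y[use])
    res <- y[use] - Xu %*% beta
    df <- n_used[i] - ncol(Xu)
    sigma2 <- sum(res^2) / df
    XtXinv <- chol2inv(qr.R(qx))
    gp <- match(2L, qx$pivot)
    se <- sqrt(sigma2 * XtXinv[gp, gp])
    slope[i] <- beta["meth"]
    pval[i] <- 2 * stats::pt(-abs(beta["meth"] / se), df)
  }
  out <- data.table::data.table(
    pairs, tile_id = tile_ids(x)[pairs$tile_idx],
    slope = slope, p = pval,
    fdr = stats::p.adjust(pval, method = "BH"),
    n_used = n_used, skipped = skipped)
  out[, sign := ifelse(slope > 0, "positive", "negative")]
  out[, significant := !is.na(fdr) & fdr < fdr_cut]
  out[]
}

#' Cross-tabulate eQTMs against DMRs
#'
#' Flags eQTM tiles overlapping a DMR (same tile coordinates), and
#' summarises positive/negative association shares overall and among
#' DMR-overlapping tiles, by DMR direction.
#'
#' @param eqtms [fit_eqtm()] table (typically the significant subset).
#' @param dmr_records One or more DMR tables ([test_tiles()]) --
#'   concatenated with `rbind` if several contrasts.
#' @return List: `eqtms` (with `overlaps_dmr` flag), `summary`
#'   (`n_unique_tiles`, `n_overlap`, `overlap_pct`, sign shares), and
#'   `by_direction` cross-tab.
#' @export
eqtm_dmr_overlap <- function(eqtms, dmr_records) {
  dmr <- data.table::as.data.table(dmr_records)
  dmr_tiles <- if (nrow(dmr) > 0)
    unique(paste0(dmr$chrom, ":", dmr$start, "-", dmr$end)[dmr$is_dmr])
  else character()
  eq <- data.table::as.data.table(eqtms)
  eq[, overlaps_dmr := tile_id %in% dmr_tiles]
  u_tiles <- unique(eq$tile_id)
  u_overlap <- unique(eq$tile_id[eq$overlaps_dmr])
  summary <- data.frame(
    n_unique_tiles = length(u_tiles),
    n_overlap = length(u_overlap),
    overlap_pct = pct_share(length(u_overlap), length(u_tiles)),
    negative_pct_all = pct_share(sum(eq$sign == "negative", na.rm = TRUE),
                                 sum(!is.na(eq$sign))),
    negative_pct_overlap = pct_share(
      sum(eq$sign == "negative" & eq$overlaps_dmr, na.rm = TRUE),
      sum(eq$overlaps_dmr & !is.na(eq$sign))))
  by_dir <- NULL
  if (nrow(dmr) > 0 && any(eq$overlaps_dmr)) {
    dsub <- dmr[dmr$is_dmr,
                .(tile_id = paste0(chrom, ":", start, "-", end), direction)]
    merged <- merge(eq[eq$overlaps_dmr], unique(dsub), by = "tile_id",
                    allow.cartesian = TRUE)
    by_dir <- as.data.frame(table(direction = merged$direction,
                                  sign = merged$sign))
  }
  list(eqtms = eq[], summary = summary, by_direction = by_dir)
}
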