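#' Two-group design with covariates
#'
#' Builds the design used by the differential-methylation test: the two
#' sample groups of a contrast plus a covariate model matrix (sex, age,
#' smoking status, stage, viral expression level, ... as configured).
#' Factor-like covariates are expanded via [stats::model.matrix()];
#' continuous covariates are passed through.
#'
#' @param metadata `data.frame` with a `sample` column and the grouping
#'   and covariate columns.
#' @param groupA,groupB Values of `group_col` defining the contrast
#'   (`groupA` is the first-named group: positive differences mean
#'   hypermethylation in `groupA`).
#' @param group_col Name of the grouping column (default `"subtype"`).
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @return A `group_design` list: `samplesA`, `samplesB`, `covariates`
#'   (numeric matrix over `c(samplesA, samplesB)` or NULL), `contrast`.
#' @export
group_design <- function(metadata, groupA, groupB, group_col = "subtype",
                         covariates = character()) {
  stop_if(!"sample" %in% names(metadata), "metadata needs a 'sample' column")
  sA <- metadata$sample[metadata[[group_col]] == groupA]
  sB <- metadata$sample[metadata[[group_col]] == groupB]
  stop_if(length(sA) == 0 || length(sB) == 0,
          "empty group in contrast ", groupA, " vs ", groupB)
  stop_if(length(intersect(sA, sB)) > 0, "groups overlap")
  X <- NULL
  if (length(covariates) > 0) {
    md <- metadata[match(c(sA, sB), metadata$sample), covariates, drop = FALSE]
    X <- stats::model.matrix(~ ., data = md)[, -1, drop = FALSE]
    rownames(X) <- c(sA, sB)
  }
  structure(list(samplesA = sA, samplesB = sB, covariates = X,
                 contrast = paste0(groupA, "_vs_", groupB)),
            class = "group_design")
}

#' Tiles eligible for differential testing
#'
#' A tile is interrogated only when it has non-missing counts in at
#' least `min_frac` of the samples of *each* group (ceiling at
#' non-integer thresholds, the stricter reading).
#'
#' @param x A `meth_tiles` object.
#' @param design A [group_design()].
#' @param min_frac Minimum per-group covered fraction (default 0.8).
#' @return Logical vector over tiles.
#' @export
eligible_tiles <- function(x, design, min_frac = 0.8) {
  stopifnot(inherits(x, "meth_tiles"))
  covA <- rowSums(!is.na(x$total[, design$samplesA, drop = FALSE]))
  covB <- rowSums(!is.na(x$total[, design$samplesB, drop = FALSE]))
  ok <- covA >= ceiling(min_frac * length(design$samplesA)) &
    covB >= ceiling(min_frac * length(design$samplesB))
  stop_if(!any(ok),
          "no tile passes the per-group coverage rule; coverage too sparse")
  ok
}

#' Beta-binomial dispersion with empirical-Bayes shrinkage
#'
#' Per-tile method-of-moments estimate of the intraclass dispersion
#' `phi` (the beta-binomial overdispersion: `Var(m/t) =
#' p(1-p)(1+(t-1)phi)/t`), computed from residuals around the two group
#' means, then shrunk toward the genome-wide median with weight
#' `w = m/(m + k)` where `m` is the tile's total coverage. Tiles with
#' degenerate residual information (group mean 0 or 1) take the prior.
#'
#' @param x A `meth_tiles` object (typically already subset to eligible
#'   tiles).
#' @param design A [group_design()].
#' @param k Shrinkage tuning constant; larger `k` pulls harder toward
#'   the prior. Default `2 * median(m)` (weight 1/3 at median coverage).
#' @return A `dispersion_model` list: `phi_raw`, `phi`, `prior`,
#'   `weight`, `k`.
#' @export
estimate_dispersion <- function(x, design, k = NULL) {
  stopifnot(inherits(x, "meth_tiles"))
  num <- 0; den <- 0; m <- 0
  for (ss in list(design$samplesA, design$samplesB)) {
    Tg <- x$total[, ss, drop = FALSE]
    Mg <- x$meth[, ss, drop = FALSE]
    tg <- rowSums(Tg, na.rm = TRUE)
    pg <- rowSums(Mg, na.rm = TRUE) / tg
    P <- Mg / Tg
    cg <- rowSums(!is.na(Tg))
    # cg/(cg-1) undoes the df lost to the estimated group mean
    num <- num + ifelse(cg > 1, cg / (cg - 1), 1) *
      rowSums((P - pg)^2, na.rm = TRUE) -
      pg * (1 - pg) * rowSums(1 / Tg, na.rm = TRUE)
    den <- den + pg * (1 - pg) * rowSums((Tg - 1) / Tg, na.rm = TRUE)
    m <- m + tg
  }
  phi_raw <- ifelse(den > 0, num / den, NA_real_)
  phi_raw <- clip01(phi_raw, 1e-6, 0.999)
  prior <- stats::median(phi_raw, na.rm = TRUE)
  if (!is.finite(prior)) prior <- 0.05
  if (is.null(k)) k <- 2 * stats::median(m)
  w <- m / (m + k)
  phi <- clip01(w * ifelse(is.na(phi_raw), prior, phi_raw) + (1 - w) * prior,
                1e-6, 0.999)
  structure(list(phi_raw = phi_raw, phi = phi, prior = prior,
                 weight = w, k = k),
            class = "dispersion_model")
}

#' Covariate-adjusted beta-binomial differential methylation test
#'
#' For each eligible tile, per-sample methylation fractions are taken
#' through the variance-stabilising arcsine link
#' `y = asin(2p - 1)`, whose approximate variance under the
#' beta-binomial is `(1 + (t-1)phi) / t` -- free of `p`. The group
#' effect is then a Wald test of the group coefficient in a weighted
#' least-squares fit of `y` on group + covariates with inverse-variance
#' weights, using the shrunken dispersion. Rank-deficient covariates
#' within a tile are dropped (noted); p-values use a t reference with
#' residual degrees of freedom.
#'
#' @param x A `meth_tiles` object.
#' @param design A [group_design()].
#' @param dispersion Optional [estimate_dispersion()] result for the
#'   eligible tiles; computed if `NULL`.
#' @param fdr_cut,min_diff_pp DMR selection rule: BH-adjusted p below
#'   `fdr_cut` (default 0.05) and absolute group difference of at least
#'   `min_diff_pp` percentage points (default 20).
#' @param min_frac Per-group coverage eligibility fraction.
#' @return `data.table` of DMR records: tile coordinates, `mean_a`,
#'   `mean_b` (coverage-weighted group means), `diff_pp`, `stat`, `p`,
#'   `fdr`, `direction` (`hyper`/`hypo` w.r.t. group A), `is_dmr`,
#'   `note`. Attribute `n_tested`.
#' @export
test_tiles <- function(x, design, dispersion = NULL,
                       fdr_cut = 0.05, min_diff_pp = 20, min_frac = 0.8) {
  ok <- eligible_tiles(x, design, min_frac)
  xt <- subset_tiles(x, which(ok), c(design$samplesA, design$samplesB))
  if (is.null(dispersion)) dispersion <- estimate_dispersion(xt, design)
  sa <- design$samplesA; sb <- design$samplesB
  grp <- c(rep(1, length(sa)), rep(0, length(sb)))
  Xc <- design$covariates
  if (!is.null(Xc)) Xc <- Xc[c(sa, sb), , drop = FALSE]
  n <- nrow(xt$tiles)
  P <- xt$meth / xt$total
  Tt <- xt$total
  ta <- rowSums(Tt[, sa, drop = FALSE], na.rm = TRUE)
  tb <- rowSums(Tt[, sb, drop = FALSE], na.rm = TRUE)
  mean_a <- rowSums(xt$meth[, sa, drop = FALSE], na.rm = TRUE) / ta
  mean_b <- rowSums(xt$meth[, sb, drop = FALSE], na.rm = TRUE) / tb
  stat <- rep(NA_real_, n); pval <- rep(NA_real_, n)
  note <- rep("", n)
  Xfull <- cbind(intercept = 1, group = grp, Xc)
  for (i in seq_len(n)) {
    use <- which(!is.na(Tt[i, ]))
    t_i <- Tt[i, use]
    y <- asin(2 * P[i, use] - 1)
    w <- t_i / (1 + (t_i - 1) * dispersion$phi[i])
    Xi <- Xfull[use, , drop = FALSE]
    qx <- qr(Xi * sqrt(w))
    if (qx$rank < ncol(Xi)) {
      keep_cols <- qx$pivot[seq_len(qx$rank)]
      if (!(2 %in% keep_cols)) { note[i] <- "group_aliased"; next }
      Xi <- Xi[, sort(keep_cols), drop = FALSE]
      qx <- qr(Xi * sqrt(w))
      note[i] <- "covariate_dropped"
    }
    gi <- which(colnames(Xi) == "group")
    beta <- qr.coef(qx, y * sqrt(w))
    XtWXinv <- chol2inv(qr.R(qx))
    gp <- match(gi, qx$pivot)
    se <- sqrt(XtWXinv[gp, gp])
    stat[i] <- beta[gi] / se
    df <- length(use) - ncol(Xi)
    pval[i] <- 2 * stats::pt(-abs(stat[i]), df = max(df, 1))
  }
  fdr <- stats::p.adjust(pval, method = "BH")
  diff_pp <- (mean_a - mean_b) * 100
  rec <- data.table::data.table(
    xt$tiles,
    mean_a = mean_a, mean_b = mean_b, diff_pp = diff_pp,
    stat = stat, p = pval, fdr = fdr,
    direction = ifelse(diff_pp > 0, "hyper", "hypo"),
    is_dmr = !is.na(fdr) & fdr < fdr_cut & abs(diff_pp) >= min_diff_pp,
    note = note
  )
  data.table::setattr(rec, "n_tested", n)
  data.table::setattr(rec, "contrast", design$contrast)
  rec[]
}

#' Summarise a DMR table (counts and integer percentages)
#'
#' The cohort-style audit row: number of tested tiles, hyper- and
#' hypo-DMR counts with their shares among DMRs, and the total DMR
#' share among tested tiles, all as integer-rounded percentages.
#'
#' @param records DMR `data.table` from [test_tiles()], or `NULL` when
#'   supplying printed counts directly.
#' @param contrast Contrast label.
#' @param n_tested,n_hyper,n_hypo Direct counts (used when `records`
#'   is `NULL`, e.g. to recompute a published table row).
#' @return One-row `data.frame`: `contrast`, `n_tested`, `n_hyper`,
#'   `hyper_pct`, `n_hypo`, `hypo_pct`, `n_dmr`, `dmr_pct`,
#'   `no_dmr_flag`.
#' @export
summarize_dmrs <- function(records = NULL, contrast = NULL,
                           n_tested = NULL, n_hyper = NULL, n_hypo = NULL) {
  if (!is.null(records)) {
    n_tested <- attr(records, "n_tested") %||% nrow(records)
    contrast <- contrast %||% attr(records, "contrast")
    n_hyper <- sum(records$is_dmr & records$direction == "hyper", na.rm = TRUE)
    n_hypo <- sum(records$is_dmr & records$direction == "hypo", na.rm = TRUE)
  }
  n_dmr <- n_hyper + n_hypo
  data.frame(contrast = contrast %||% "", n_tested = n_tested,
             n_hyper = n_hyper, hyper_pct = pct_share(n_hyper, n_dmr),
             n_hypo = n_hypo, hypo_pct = pct_share(n_hypo, n_dmr),
             n_dmr = n_dmr, dmr_pct = pct_share(n_dmr, n_tested),
             no_dmr_flag = n_dmr == 0)
}
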