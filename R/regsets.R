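#' Center-anchored methylation profile over a region set
#'
#' Aggregates tile methylation into an odd number of equal-width bins
#' spanning `center - flank_bp` to `center + flank_bp` around each
#' region's midpoint, coverage-weighted over all regions, per sample.
#' Minus-strand regions are flipped. Regulatory activity shows up as a
#' central dip: bound, active regions are locally unmethylated.
#'
#' @param x A `meth_tiles` object.
#' @param regions Region set (`chrom`, `start`, `end[, strand]`).
#' @param n_bins Odd number of bins (default 21).
#' @param flank_bp Half-window width, bp (default 5000).
#' @return List of class `mira_profile`: `profile` (bins x samples),
#'   `bin_width_bp`, `n_regions_used`, `offsets` (bin centers, bp).
#' @export
mira_profile <- function(x, regions, n_bins = 21L, flank_bp = 5000L) {
  stopifnot(inherits(x, "meth_tiles"))
  stop_if(n_bins %% 2 == 0, "n_bins must be odd")
  bw <- 2 * flank_bp / n_bins
  mid <- x$tiles$start + (x$tiles$end - x$tiles$start) / 2
  ns <- length(x$samples)
  msum <- matrix(0, n_bins, ns); tsum <- matrix(0, n_bins, ns)
  meth0 <- x$meth; total0 <- x$total
  meth0[is.na(meth0)] <- 0; total0[is.na(total0)] <- 0
  used <- 0L
  for (k in seq_len(nrow(regions))) {
    ctr <- (regions$start[k] + regions$end[k]) / 2
    sel <- which(x$tiles$chrom == regions$chrom[k] &
                   abs(mid - ctr) < flank_bp)
    if (length(sel) == 0) next
    used <- used + 1L
    bin <- pmin(n_bins, 1L + floor((mid[sel] - ctr + flank_bp) / bw))
    if ("strand" %in% names(regions) &&
        identical(regions$strand[k], "-")) bin <- n_bins + 1L - bin
    msum <- msum + add_bins(meth0[sel, , drop = FALSE], bin, n_bins)
    tsum <- tsum + add_bins(total0[sel, , drop = FALSE], bin, n_bins)
  }
  stop_if(used == 0, "no region overlaps a covered tile")
  prof <- msum / tsum
  prof[tsum == 0] <- NA
  colnames(prof) <- x$samples
  structure(list(profile = prof, bin_width_bp = bw,
                 n_regions_used = used,
                 offsets = (seq_len(n_bins) - (n_bins + 1) / 2) * bw),
            class = "mira_profile")
}

#' Regulatory-activity score from a methylation dip profile
#'
#' `score = log2(shoulder / center)` per sample, where the shoulder is
#' the mean of the two bins at `shoulder_offset` bins from the center.
#' A flat profile scores exactly 0; deeper central dips (stronger
#' inferred binding/activity) score higher. Centers of 0 are floored
#' at `floor_center` (flagged).
#'
#' @param profile A `mira_profile`.
#' @param shoulder_offset Bins from center to the shoulder; default
#'   `floor(B / 2)` where `B` is the flank bin count.
#' @param floor_center Center floor (default 1e-3).
#' @return `data.frame(sample, score, center, shoulder, floored)`.
#' @export
mira_score <- function(profile, shoulder_offset = NULL,
                       floor_center = 1e-3) {
  stopifnot(inherits(profile, "mira_profile"))
  p <- profile$profile
  n_bins <- nrow(p)
  ctr_i <- (n_bins + 1L) %/% 2L
  B <- (n_bins - 1L) %/% 2L
  shoulder_offset <- shoulder_offset %||% max(1L, B %/% 2L)
  stop_if(shoulder_offset < 1 || shoulder_offset > B,
          "shoulder_offset out of range")
  ctr <- p[ctr_i, ]
  sh <- colMeans(p[c(ctr_i - shoulder_offset, ctr_i + shoulder_offset), ,
                   drop = FALSE], na.rm = TRUE)
  stop_if(any(is.na(ctr)) || any(is.na(sh)),
          "center or shoulder bin missing for some sample")
  floored <- ctr < floor_center
  ctr2 <- pmax(ctr, floor_center)
  data.frame(sample = colnames(p), score = log2(sh / ctr2),
             center = ctr, shoulder = sh, floored = floored,
             row.names = NULL)
}

#' Reference-based deconvolution of a bulk methylome
#'
#' Non-negative least squares of the observed region methylation on
#' the cell-type atlas; fractions are normalised to the simplex. The
#' tumor fraction is either the coefficient of a designated
#' tumor-like reference row (`tumor_like`, typically the epithelial
#' lineage the cancer derives from) or, when `tumor_like` is `NULL`,
#' the unexplained complement `max(0, 1 - sum(w))`. Cancer
#' cell-specific methylation is then solved per region as
#' `(observed - sum(normal contributions)) / w_tumor`, clipped to
#' [0, 1]; it is reported missing when `w_tumor < min_tumor`
#' (unstable division).
#'
#' @param sample_meth Named per-region methylation fractions.
#' @param atlas Cell types x regions reference matrix.
#' @param tumor_like Name of the atlas row treated as the tumor-like
#'   basis, or `NULL`.
#' @param min_tumor Minimum tumor fraction for the cancer-specific
#'   solve (default 0.05).
#' @return List of class `deconvolution_result`: `fractions` (named,
#'   sums to 1, includes `tumor`), `cancer_specific_meth` (per-region,
#'   or `NULL`), `cancer_meth_mean`, `n_clipped`, `resid_rmse`.
#' @export
deconvolve <- function(sample_meth, atlas, tumor_like = "epithelial",
                       min_tumor = 0.05) {
  regions <- intersect(names(sample_meth), colnames(atlas))
  stop_if(length(regions) < nrow(atlas) + 1,
          "need at least as many regions as atlas components")
  y <- sample_meth[regions]
  A <- t(atlas[, regions, drop = FALSE])     # regions x cell types
  w <- pracma::lsqnonneg(A, y)$x
  names(w) <- rownames(atlas)
  if (!is.null(tumor_like)) {
    stop_if(!tumor_like %in% rownames(atlas),
            "tumor_like row absent from atlas")
    w <- w / max(sum(w), 1e-12)
    w_tumor <- w[[tumor_like]]
    normals <- setdiff(rownames(atlas), tumor_like)
  } else {
    if (sum(w) > 1) w <- w / sum(w)
    w_tumor <- max(0, 1 - sum(w))
    normals <- rownames(atlas)
  }
  fitted_normal <- as.numeric(A[, normals, drop = FALSE] %*% w[normals])
  cancer <- NULL; n_clipped <- 0L; cmean <- NA_real_
  if (w_tumor >= min_tumor) {
    raw <- (y - fitted_normal) / w_tumor
    n_clipped <- sum(raw < 0 | raw > 1)
    cancer <- clip01(raw)
    names(cancer) <- regions
    cmean <- mean(cancer)
  }
  fr <- c(stats::setNames(w[normals], normals), tumor = unname(w_tumor))
  fr <- fr / sum(fr)
  fit <- fitted_normal + if (is.null(cancer)) w_tumor *
    mean(y) else w_tumor * cancer
  structure(list(fractions = fr, cancer_specific_meth = cancer,
                 cancer_meth_mean = cmean, n_clipped = n_clipped,
                 resid_rmse = sqrt(mean((y - fit)^2))),
            class = "deconvolution_result")
}

#' Deconvolve every sample of a cohort
#'
#' @param meth Regions x samples methylation matrix.
#' @param atlas Cell types x regions reference matrix.
#' @param ... Passed to [deconvolve()].
#' @return List: `fractions` (samples x components), `cancer_meth_mean`
#'   (named vector, `NA` where unstable), `results` (per-sample
#'   `deconvolution_result`s).
#' @export
deconvolve_cohort <- function(meth, atlas, ...) {
  res <- lapply(colnames(meth), function(s)
    deconvolve(stats::setNames(meth[, s], rownames(meth)), atlas, ...))
  names(res) <- colnames(meth)
  fr <- do.call(rbind, lapply(res, `[[`, "fractions"))
  list(fractions = fr,
       cancer_meth_mean = vapply(res, `[[`, numeric(1),
                                 "cancer_meth_mean"),
       results = res)
}

#' Per-sample expression pathway score
#'
#' Each gene's log2-CPM is z-scored across the cohort; the pathway
#' score is the mean z-score over the set's genes.
#'
#' @param expression Genes x samples matrix.
#' @param gene_set Character vector of gene ids.
#' @param set_name Label carried through.
#' @return `data.frame(sample, set, score)`; cohort mean of `score`
#'   is 0 by construction.
#' @export
pathway_score <- function(expression, gene_set, set_name = "set") {
  found <- intersect(gene_set, rownames(expression))
  missing <- setdiff(gene_set, found)
  if (length(missing) > 0)
    message(length(missing), " gene(s) absent from expression matrix")
  stop_if(length(found) < 2, "fewer than 2 set genes in the matrix")
  E <- expression[found, , drop = FALSE]
  z <- (E - rowMeans(E)) / apply(E, 1, stats::sd)
  data.frame(sample = colnames(E), set = set_name,
             score = colMeans(z), row.names = NULL)
}
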