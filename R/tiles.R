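#' Tile CpG sites into fixed 100-bp windows
#'
#' Each CpG (1-based position `p`) is assigned to the genome-anchored
#' window `[floor((p-1)/100)*100, +100)` and per-sample counts are
#' summed within windows. Windows with no surviving CpG are absent.
#' Tiling trades single-CpG resolution for coverage: summed counts make
#' the beta-binomial group test far better powered at typical WGBS
#' depth.
#'
#' @param x A (filtered) `cpg_counts` object.
#' @param tile_bp Window width in bp (100 by default).
#' @return A `meth_tiles` object: `tiles` (data.table `chrom`, `start`,
#'   `end` 0-based half-open, `n_cpgs`), `meth`/`total` (tiles x samples,
#'   `NA` where a sample has no covered CpG in the tile), `samples`, and
#'   attribute `mean_coverage` (mean per-sample tile depth over covered
#'   entries).
#' @export
tile_100bp <- function(x, tile_bp = 100L) {
  stopifnot(inherits(x, "cpg_counts"))
  tile_start <- (x$sites$pos - 1L) %/% tile_bp * tile_bp
  key <- paste(x$sites$chrom, tile_start)
  grp <- match(key, unique(key))
  meth0 <- x$meth; total0 <- x$total
  covered <- !is.na(total0)
  meth0[!covered] <- 0L; total0[!covered] <- 0L
  meth <- rowsum(meth0, grp, reorder = FALSE)
  total <- rowsum(total0, grp, reorder = FALSE)
  ncpg <- as.integer(rowsum(rep(1L, length(grp)), grp, reorder = FALSE))
  first <- !duplicated(grp)
  tiles <- data.table::data.table(
    chrom = x$sites$chrom[first],
    start = tile_start[first],
    end = tile_start[first] + as.integer(tile_bp),
    n_cpgs = ncpg
  )
  none <- rowsum((!covered) * 1L, grp, reorder = FALSE) == ncpg
  meth[none] <- NA_integer_
  total[none] <- NA_integer_
  o <- order(tiles$chrom, tiles$start)
  tiles <- tiles[o]
  meth <- meth[o, , drop = FALSE]; total <- total[o, , drop = FALSE]
  rownames(meth) <- rownames(total) <- NULL
  colnames(meth) <- colnames(total) <- x$samples
  out <- structure(list(tiles = tiles, meth = meth, total = total,
                        samples = x$samples),
                   class = "meth_tiles")
  attr(out, "mean_coverage") <- mean(total[!is.na(total)])
  out
}

#' Per-sample methylation fractions of tiles
#'
#' @param x A `meth_tiles` object.
#' @return Tiles x samples matrix of `meth/total` (`NA` where uncovered).
#' @export
meth_fraction <- function(x) {
  stopifnot(inherits(x, "meth_tiles"))
  x$meth / x$total
}

tile_ids <- function(x) paste0(x$tiles$chrom, ":", x$tiles$start, "-", x$tiles$end)

#' Genome-wide methylation level per sample
#'
#' Coverage-weighted global methylation: total methylated reads over
#' total reads, per sample (invariant under tiling by count
#' conservation).
#'
#' @param x A `cpg_counts` or `meth_tiles` object.
#' @return Named per-sample fractions.
#' @export
global_methylation <- function(x) {
  colSums(x$meth, na.rm = TRUE) / colSums(x$total, na.rm = TRUE)
}

#' Subset a meth_tiles object
#' @param x A `meth_tiles` object.
#' @param i Row (tile) index.
#' @param samples Optional sample subset.
#' @return The subsetted `meth_tiles`.
#' @export
subset_tiles <- function(x, i, samples = NULL) {
  samples <- samples %||% x$samples
  structure(list(tiles = x$tiles[i],
                 meth = x$meth[i, samples, drop = FALSE],
                 total = x$total[i, samples, drop = FALSE],
                 samples = samples),
            class = "meth_tiles")
}

#' Binned metagene methylation profile over a region set
#'
#' Regions are scaled to a common length split into `body_bins` bins;
#' flanks of `flank_bp` on each side are binned at fixed `flank_bin_bp`
#' resolution. Tiles are assigned to bins by midpoint and averaged with
#' coverage weights, per sample. Minus-strand regions are flipped so the
#' profile reads 5'->3'.
#'
#' @param x A `meth_tiles` object.
#' @param regions `data.frame(chrom, start, end[, strand])`, 0-based
#'   half-open.
#' @param flank_bp Flank width on each side (default 2000).
#' @param body_bins Number of bins across the scaled region body.
#' @param flank_bin_bp Bin width in the flanks.
#' @return List: `profile` (bins x samples matrix of weighted mean
#'   methylation), `bins` (data.table with `zone` up/body/down and
#'   `index`), `scalar` (per-sample coverage-weighted mean over all
#'   tiles overlapping any region or flank), `n_regions_used`,
#'   `n_regions_empty`.
#' @export
region_mean_methylation <- function(x, regions, flank_bp = 2000L,
                                    body_bins = 20L, flank_bin_bp = 200L) {
  stopifnot(inherits(x, "meth_tiles"))
  nf <- as.integer(flank_bp %/% flank_bin_bp)
  nb <- as.integer(body_bins)
  nbin <- 2L * nf + nb
  ns <- length(x$samples)
  msum <- matrix(0, nbin, ns); tsum <- matrix(0, nbin, ns)
  mid <- x$tiles$start + (x$tiles$end - x$tiles$start) / 2
  meth0 <- x$meth; total0 <- x$total
  meth0[is.na(meth0)] <- 0; total0[is.na(total0)] <- 0
  used <- 0L; empty <- 0L
  touched <- rep(FALSE, nrow(x$tiles))
  for (k in seq_len(nrow(regions))) {
    rc <- regions$chrom[k]; rs <- regions$start[k]; re <- regions$end[k]
    minus <- "strand" %in% names(regions) && identical(regions$strand[k], "-")
    sel <- which(x$tiles$chrom == rc & mid >= rs - flank_bp & mid < re + flank_bp)
    if (length(sel) == 0) { empty <- empty + 1L; next }
    used <- used + 1L
    touched[sel] <- TRUE
    m <- mid[sel]
    bin <- integer(length(sel))
    up <- m < rs; dn <- m >= re
    body <- !up & !dn
    bin[up] <- nf - pmin(nf - 1L, floor((rs - m[up]) / flank_bin_bp))
    bin[body] <- nf + 1L + pmin(nb - 1L, floor((m[body] - rs) / (re - rs) * nb))
    bin[dn] <- nf + nb + 1L + pmin(nf - 1L, floor((m[dn] - re) / flank_bin_bp))
    if (minus) bin <- nbin + 1L - bin
    msum <- msum + add_bins(meth0[sel, , drop = FALSE], bin, nbin)
    tsum <- tsum + add_bins(total0[sel, , drop = FALSE], bin, nbin)
  }
  prof <- msum / tsum
  prof[tsum == 0] <- NA
  colnames(prof) <- x$samples
  wt <- total0[touched, , drop = FALSE]
  scalar <- colSums(meth0[touched, , drop = FALSE]) / colSums(wt)
  zone <- c(rep("upstream", nf), rep("body", nb), rep("downstream", nf))
  list(profile = prof,
       bins = data.table::data.table(index = seq_len(nbin), zone = zone),
       scalar = scalar, n_regions_used = used, n_regions_empty = empty)
}

add_bins <- function(mat, bin, nbin) {
  out <- matrix(0, nbin, ncol(mat))
  agg <- rowsum(mat, bin, reorder = TRUE)
  out[as.integer(rownames(agg)), ] <- agg
  out
}
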