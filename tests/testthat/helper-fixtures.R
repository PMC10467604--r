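# shared fixtures, built once per test run

# small genome, full 36-sample cohort with planted structure
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- suppressWarnings(simulate_cohort(sim_config(
        n_chroms = 1L, chrom_len_bp = 200000L, n_dmr_blocks = 25L,
        n_genes = 20L, n_eqtm_genes = 8L, n_atlas_regions = 150L,
        n_regset_regions = 10L,
        seed = 42L)))
    }
    cache
  }
})

small_cohort_dir <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- file.path(tempdir(), "methylotype-small-cohort")
      write_cohort(small_cohort(), d)
      cache <<- d
    }
    cache
  }
})

# meth_tiles object straight from count matrices
make_tiles <- function(meth, total, chrom = "chr1", samples = NULL) {
  samples <- samples %||% paste0("s", seq_len(ncol(total)))
  dimnames(meth) <- dimnames(total) <- list(NULL, samples)
  structure(list(
    tiles = data.table::data.table(
      chrom = chrom, start = (seq_len(nrow(total)) - 1L) * 100L,
      end = seq_len(nrow(total)) * 100L, n_cpgs = 1L),
    meth = meth, total = total, samples = samples),
    class = "meth_tiles")
}

two_group_design <- function(n_a, n_b) {
  structure(list(samplesA = paste0("s", seq_len(n_a)),
                 samplesB = paste0("s", n_a + seq_len(n_b)),
                 covariates = NULL, contrast = "A_vs_B"),
            class = "group_design")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

clip01 <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

# independent two-sided Fisher p by hypergeometric enumeration
fisher_p_oracle <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  ks <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(ks, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# independent instability oracle: plain per-segment loop
instability_oracle <- function(segments, arms, min_len = 10e6,
                               arm_frac = 0.9, band = 0.3) {
  score <- 0
  for (i in seq_len(nrow(segments))) {
    for (k in seq_len(nrow(arms))) {
      if (segments$chrom[i] != arms$chrom[k]) next
      s <- max(segments$start[i], arms$start[k])
      e <- min(segments$end[i], arms$end[k])
      if (e <= s) next
      dev <- abs(segments$copy_number[i] - 2)
      if (dev < band) next
      len <- e - s
      if (len <= min_len) next
      if (len >= arm_frac * (arms$end[k] - arms$start[k]))
        score <- score + dev
      else score <- score + 1
    }
  }
  score
}
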