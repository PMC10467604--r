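test_that("the 80% per-group coverage rule uses a ceiling", {
  # group A n=8: 6 covered < ceiling(6.4) = 7 -> excluded
  # group B n=10: 8 covered = ceiling(8) -> kept when A is fine
  total <- matrix(30L, 3, 18)
  total[1, 1:2] <- NA          # tile 1: A covered 6/8
  total[2, 9:10] <- NA         # tile 2: B covered 8/10
  meth <- matrix(10L, 3, 18); meth[is.na(total)] <- NA
  tl <- make_tiles(meth, total)
  des <- two_group_design(8, 10)
  ok <- eligible_tiles(tl, des)
  expect_equal(unname(ok), c(FALSE, TRUE, TRUE))
  tl$total[] <- NA_integer_
  expect_error(eligible_tiles(tl, des), "sparse")
})

test_that("dispersion estimation floors degenerate tiles and obeys the shrinkage limit", {
  total <- matrix(40L, 5, 18)
  meth <- matrix(20L, 5, 18)     # identical counts: no residual variance
  tl <- make_tiles(meth, total)
  des <- two_group_design(8, 10)
  dm <- estimate_dispersion(tl, des)
  expect_true(all(dm$phi_raw <= 1e-6 + 1e-12))
  expect_true(all(dm$phi > 0 & dm$phi < 1))
  dm_inf <- estimate_dispersion(tl, des, k = 1e12)
  expect_equal(unname(dm_inf$phi), rep(dm_inf$prior, 5), tolerance = 1e-6)
})

test_that("dispersion is recovered from simulated counts", {
  x <- simulate_tile_counts(2000, coverage = 24, phi = 0.1, seed = 21)
  dm <- estimate_dispersion(x, attr(x, "design"))
  expect_gt(median(dm$phi), 0.05)
  expect_lt(median(dm$phi), 0.2)
})

test_that("identical count vectors in both groups give zero difference and no DMR", {
  counts <- matrix(rep(c(5L, 9L, 14L), 6), 1)   # same 9 values per group
  total <- matrix(20L, 1, 18)
  tl <- make_tiles(counts, total)
  rec <- test_tiles(tl, two_group_design(9, 9))
  expect_equal(rec$diff_pp, 0)
  expect_gt(rec$p, 0.9)
  expect_false(rec$is_dmr)
})

test_that("swapping the groups negates the difference and keeps p", {
  x <- simulate_tile_counts(150, effect_pp = 25, n_planted = 30,
                            seed = 13)
  des <- attr(x, "design")
  des_swap <- structure(list(samplesA = des$samplesB,
                             samplesB = des$samplesA,
                             covariates = NULL, contrast = "B_vs_A"),
                        class = "group_design")
  r1 <- test_tiles(x, des)
  r2 <- test_tiles(x, des_swap)
  expect_equal(r2$diff_pp, -r1$diff_pp)
  expect_equal(r2$p, r1$p, tolerance = 1e-10)
  flip <- c(hyper = "hypo", hypo = "hyper")
  expect_equal(r2$direction[r1$is_dmr],
               unname(flip[r1$direction[r1$is_dmr]]))
})

test_that("the DMR set is invariant to tile order and FDR is monotone in p", {
  x <- simulate_tile_counts(200, effect_pp = 30, n_planted = 40, seed = 3)
  des <- attr(x, "design")
  r1 <- test_tiles(x, des)
  perm <- sample(nrow(x$tiles))
  xp <- subset_tiles(x, perm)
  r2 <- test_tiles(xp, des)
  key <- function(r) sort(paste0(r$chrom, ":", r$start)[r$is_dmr])
  expect_equal(key(r1), key(r2))
  o <- order(r1$p)
  expect_true(all(diff(r1$fdr[o]) >= -1e-12))
})

test_that("covariate-adjusted testing absorbs a covariate-driven shift", {
  # methylation depends on a binary covariate, not on group
  set.seed(5)
  ns <- 18
  cov_bin <- c(rep(1, 6), rep(0, 2), rep(1, 2), rep(0, 8))  # confounded
  mu <- 0.35 + 0.4 * cov_bin
  total <- matrix(rnbinom(400 * ns, mu = 30, size = 8) + 1L, 400, ns)
  p <- matrix(rbeta(400 * ns, rep(mu, each = 400) * 9,
                    (1 - rep(mu, each = 400)) * 9), 400, ns)
  meth <- matrix(rbinom(400 * ns, total, p), 400, ns)
  tl <- make_tiles(meth, total)
  des <- two_group_design(8, 10)
  r_raw <- test_tiles(tl, des)
  des$covariates <- matrix(cov_bin, ns, 1,
                           dimnames = list(tl$samples, "cv"))
  r_adj <- test_tiles(tl, des)
  expect_gt(mean(r_raw$p < 0.05, na.rm = TRUE), 0.3)   # confounded
  expect_lt(mean(r_adj$p < 0.05, na.rm = TRUE), 0.12)  # absorbed
})

test_that("DMR summaries reproduce printed-table arithmetic", {
  s <- summarize_dmrs(contrast = "IMU_vs_HPVneg", n_tested = 3757540,
                      n_hyper = 305812, n_hypo = 14259)
  expect_equal(s$hyper_pct, 96L)
  expect_equal(s$hypo_pct, 4L)
  expect_equal(s$dmr_pct, 9L)
  z <- summarize_dmrs(contrast = "null", n_tested = 100, n_hyper = 0,
                      n_hypo = 0)
  expect_equal(z$hyper_pct, 0L)
  expect_true(z$no_dmr_flag)
})
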