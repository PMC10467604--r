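make_profile <- function(vals, ns = 1) {
  p <- matrix(rep(vals, ns), length(vals),
              dimnames = list(NULL, paste0("s", seq_len(ns))))
  structure(list(profile = p, bin_width_bp = 100,
                 n_regions_used = 10L,
                 offsets = seq_along(vals) - (length(vals) + 1) / 2),
            class = "mira_profile")
}

test_that("a uniform methylome gives a flat profile and a score of exactly 0", {
  tl <- make_tiles(matrix(12L, 60, 2), matrix(20L, 60, 2))
  reg <- data.frame(chrom = "chr1", start = c(2000L, 4000L),
                    end = c(2100L, 4100L))
  pr <- mira_profile(tl, reg, n_bins = 11L, flank_bp = 1000L)
  expect_true(all(abs(pr$profile - 0.6) < 1e-12, na.rm = TRUE))
  sc <- mira_score(pr)
  expect_identical(unname(sc$score), c(0, 0))
})

test_that("score arithmetic and monotonicity in dip depth", {
  # 11 bins, B = 5, shoulder offset 2: shoulder 0.8, center 0.2 -> 2
  vals <- rep(0.8, 11); vals[6] <- 0.2
  expect_equal(mira_score(make_profile(vals))$score, log2(4))
  deeper <- vals; deeper[6] <- 0.1
  expect_gt(mira_score(make_profile(deeper))$score,
            mira_score(make_profile(vals))$score)
  # center 0 is floored and flagged
  zero <- vals; zero[6] <- 0
  sc <- mira_score(make_profile(zero))
  expect_true(sc$floored)
  expect_true(is.finite(sc$score))
})

test_that("profiles are invariant to region order and respect strand flips", {
  set.seed(59)
  tl <- make_tiles(matrix(rbinom(200, 20, 0.5), 100, 2),
                   matrix(20L, 100, 2))
  reg <- data.frame(chrom = "chr1", start = c(2000L, 5000L, 7000L),
                    end = c(2100L, 5100L, 7100L),
                    strand = c("+", "-", "+"))
  p1 <- mira_profile(tl, reg, n_bins = 9L, flank_bp = 1000L)
  p2 <- mira_profile(tl, reg[c(3, 1, 2), ], n_bins = 9L,
                     flank_bp = 1000L)
  expect_equal(p1$profile, p2$profile)
  # flipping every strand mirrors the profile
  reg_f <- reg; reg_f$strand <- c("-", "+", "-")
  p3 <- mira_profile(tl, reg_f, n_bins = 9L, flank_bp = 1000L)
  expect_equal(p3$profile, p1$profile[9:1, , drop = FALSE])
})

test_that("planted dips are recovered from the synthetic cohort with the planted ordering", {
  co <- small_cohort()
  tl <- cohort_tiles(co)
  pr <- mira_profile(tl, as.data.frame(co$region_sets$TFBS_A),
                     n_bins = 21L, flank_bp = 2000L)
  sc <- mira_score(pr)
  ctr <- (21 + 1) / 2
  expect_lt(mean(pr$profile[ctr, ], na.rm = TRUE),
            mean(pr$profile[c(1, 21), ], na.rm = TRUE))
  # the deep-dip groups score positive; the shallow IMU dip may not
  expect_true(all(mira_score(pr)$score[co$groups != "IMU"] > 0))
  by_group <- tapply(sc$score, co$groups, mean)
  # IMU has the shallowest planted dip, hence the lowest activity
  expect_lt(by_group[["IMU"]], by_group[["KRT"]])
  expect_lt(by_group[["IMU"]], by_group[["HPVneg"]])
})

test_that("deconvolution identifies a pure reference sample", {
  set.seed(61)
  A <- matrix(runif(6 * 80, 0.05, 0.95), 6,
              dimnames = list(paste0("ct", 1:6), paste0("r", 1:80)))
  y <- A[3, ]
  d <- deconvolve(y, A, tumor_like = NULL)
  expect_gte(d$fractions[["ct3"]], 0.95)
  expect_null(d$cancer_specific_meth)   # tumor fraction ~0: unstable
})

test_that("noiseless mixtures are recovered to three decimals", {
  set.seed(67)
  A <- matrix(runif(5 * 100, 0.05, 0.95), 5,
              dimnames = list(paste0("ct", 1:5), paste0("r", 1:100)))
  w <- c(0.4, 0.3, 0.2, 0.1, 0)
  y <- as.numeric(t(A) %*% w); names(y) <- colnames(A)
  d <- deconvolve(y, A, tumor_like = NULL)
  expect_equal(unname(d$fractions[paste0("ct", 1:5)]), w,
               tolerance = 1e-3)
})

test_that("tumor fraction and cancer-specific methylation are recovered on cohort mixtures", {
  co <- small_cohort()
  dc <- deconvolve_cohort(co$mixture_meth, co$atlas)
  tf <- co$ground_truth$true_cell_fractions[, "tumor"]
  err <- dc$fractions[names(tf), "tumor"] - tf
  expect_lt(mean(abs(err)), 0.05)
  cm_err <- dc$cancer_meth_mean - co$ground_truth$tumor_meth_mean
  expect_lt(mean(abs(cm_err), na.rm = TRUE), 0.05)
})

test_that("pathway scores are cohort-centered z-means and rank planted groups", {
  set.seed(71)
  E <- matrix(rnorm(10 * 12, 5), 10,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:12)))
  ps <- pathway_score(E, paste0("g", 1:4), "set1")
  expect_equal(mean(ps$score), 0, tolerance = 1e-12)
  E2 <- E; E2[1:4, 7] <- E2[1:4, 7] + 5
  ps2 <- pathway_score(E2, paste0("g", 1:4))
  expect_equal(which.max(ps2$score), 7L)
  expect_error(pathway_score(E, c("g1", "nope")), "fewer than 2")
  co <- small_cohort()
  ker <- pathway_score(co$expression, co$gene_sets$keratinization,
                       "keratinization")
  by_group <- tapply(ker$score, co$groups, mean)
  expect_gt(by_group[["KRT"]], by_group[["IMU"]])
})
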