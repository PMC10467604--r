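test_that("the three eQTM tile filters act as specified", {
  ns <- 36
  total <- matrix(50L, 4, ns)
  total[2, 1:8] <- NA                       # covered 28/36 < 29
  meth <- matrix(25L, 4, ns)                # tile 1: constant 0.5
  meth[2, ] <- 25L
  meth[3, ] <- c(rep(0L, 34), 40L, 45L)     # 34 fully unmethylated
  meth[4, ] <- as.integer(round(seq(5, 45, length.out = ns)))
  meth[is.na(total)] <- NA
  tl <- make_tiles(meth, total)
  keep <- filter_eqtm_tiles(tl)
  expect_equal(c(keep), c(FALSE, FALSE, FALSE, TRUE))
})

test_that("cis pairing is inclusive at 1 Mb and matches a quadratic oracle", {
  set.seed(17)
  n_tiles <- 300
  tl <- make_tiles(matrix(1L, n_tiles, 2), matrix(2L, n_tiles, 2))
  tl$tiles$chrom <- sample(c("chr1", "chr2"), n_tiles, TRUE)
  tl$tiles$start <- sample(seq(0L, 3000000L, 100L), n_tiles)
  tl$tiles$end <- tl$tiles$start + 100L
  genes <- data.frame(gene = paste0("g", 1:200),
                      chrom = sample(c("chr1", "chr2"), 200, TRUE),
                      strand = sample(c("+", "-"), 200, TRUE),
                      tss = sample(0:3000000, 200))
  pairs <- cis_pairs(tl, genes, max_dist = 1e6)
  mids <- tl$tiles$start + 50
  brute <- 0L
  for (i in seq_len(n_tiles)) for (j in 1:200) {
    if (tl$tiles$chrom[i] == genes$chrom[j] &&
        abs(mids[i] - genes$tss[j]) <= 1e6) brute <- brute + 1L
  }
  expect_equal(nrow(pairs), brute)
  # boundary: midpoint exactly 1 Mb away is included, strand flips sign
  tlb <- make_tiles(matrix(1L, 1, 2), matrix(2L, 1, 2))
  tlb$tiles$start <- 1000000L - 50L + 500L; tlb$tiles$end <- tlb$tiles$start + 100L
  gb <- data.frame(gene = "g", chrom = "chr1", strand = "-", tss = 2000500L)
  pb <- cis_pairs(tlb, gb, max_dist = 1e6)
  expect_equal(nrow(pb), 1L)
  expect_equal(pb$tss_distance_bp, 1e6)   # upstream->downstream flip
  gb2 <- data.frame(gene = "g", chrom = "chr9", strand = "+", tss = 1000L)
  expect_equal(nrow(cis_pairs(tlb, gb2)), 0L)
})

test_that("an exact linear relation is recovered exactly", {
  ns <- 36
  frac <- seq(0.1, 0.9, length.out = ns)
  total <- matrix(1000L, 1, ns)
  meth <- matrix(as.integer(round(frac * 1000)), 1, ns)
  tl <- make_tiles(meth, total)
  expr <- matrix(2 * meth_fraction(tl)[1, ], 1,
                 dimnames = list("gA", tl$samples))
  pairs <- data.table::data.table(tile_idx = 1L, gene = "gA",
                                  tss_distance_bp = 0)
  fit <- fit_eqtm(pairs, tl, expr)
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_lt(fit$p, 1e-12)
  expect_equal(fit$sign, "positive")
})

test_that("the slope equals the partial-regression oracle to 10 digits", {
  set.seed(23)
  ns <- 36
  frac <- rbeta(ns, 2, 2)
  total <- matrix(1000L, 1, ns)
  tl <- make_tiles(matrix(as.integer(round(frac * 1000)), 1, ns), total)
  X <- cbind(sex = rbinom(ns, 1, 0.5), age = rnorm(ns, 60, 8),
             stage = rbinom(ns, 1, 0.4), smoking = rbinom(ns, 1, 0.5))
  rownames(X) <- tl$samples
  y <- 3 - 1.7 * meth_fraction(tl)[1, ] + 0.02 * X[, "age"] +
    0.3 * X[, "smoking"] + rnorm(ns, 0, 0.5)
  expr <- matrix(y, 1, dimnames = list("gA", tl$samples))
  pairs <- data.table::data.table(tile_idx = 1L, gene = "gA",
                                  tss_distance_bp = 0)
  fit <- fit_eqtm(pairs, tl, expr, covariates = X)
  m <- meth_fraction(tl)[1, ]
  rm_ <- stats::resid(stats::lm(m ~ X))
  ry <- stats::resid(stats::lm(y ~ X))
  oracle <- sum(rm_ * ry) / sum(rm_^2)
  expect_equal(fit$slope, oracle, tolerance = 1e-10)
  lmfit <- summary(stats::lm(y ~ m + X))
  expect_equal(fit$p, lmfit$coefficients["m", 4], tolerance = 1e-10)
})

test_that("significance is invariant to pair enumeration order", {
  set.seed(29)
  ns <- 36; nt <- 40
  frac <- matrix(rbeta(nt * ns, 2, 2), nt)
  tl <- make_tiles(matrix(as.integer(round(frac * 1000)), nt, ns),
                   matrix(1000L, nt, ns))
  expr <- matrix(rnorm(20 * ns), 20,
                 dimnames = list(paste0("g", 1:20), tl$samples))
  expr[1:5, ] <- expr[1:5, ] - 3 * frac[1:5, ]
  pairs <- data.table::data.table(
    tile_idx = rep(1:20, each = 1), gene = paste0("g", 1:20),
    tss_distance_bp = 0)
  f1 <- fit_eqtm(pairs, tl, expr)
  f2 <- fit_eqtm(pairs[sample(.N)], tl, expr)
  expect_equal(sort(f1$gene[f1$significant]),
               sort(f2$gene[f2$significant]))
})

test_that("eQTM/DMR overlap matches brute-force set intersection and printed arithmetic", {
  set.seed(37)
  n <- 1000
  tile_id <- paste0("chr1:", (0:(n - 1)) * 100, "-", (1:n) * 100)
  eq <- data.table::data.table(tile_id = tile_id,
                               sign = sample(c("positive", "negative"),
                                             n, TRUE),
                               slope = rnorm(n))
  dmr_idx <- sample(n, 240)
  dmr <- data.table::data.table(
    chrom = "chr1", start = (dmr_idx - 1) * 100, end = dmr_idx * 100,
    direction = sample(c("hyper", "hypo"), 240, TRUE), is_dmr = TRUE)
  ov <- eqtm_dmr_overlap(eq, dmr)
  brute <- length(intersect(tile_id, paste0("chr1:", dmr$start, "-",
                                            dmr$end)))
  expect_equal(ov$summary$n_overlap, brute)
  expect_true(all(ov$eqtms$overlaps_dmr ==
                    (ov$eqtms$tile_id %in% paste0("chr1:", dmr$start,
                                                  "-", dmr$end))))
  # published-scale arithmetic: 65,917 of 212,850 unique tiles -> 31%
  n2 <- 212850
  ids <- paste0("chr1:", (0:(n2 - 1)) * 100, "-", (1:n2) * 100)
  eq2 <- data.table::data.table(tile_id = ids, sign = "negative",
                                slope = -1)
  dmr2 <- data.table::data.table(chrom = "chr1",
                                 start = (0:65916) * 100,
                                 end = (1:65917) * 100,
                                 direction = "hyper", is_dmr = TRUE)
  ov2 <- eqtm_dmr_overlap(eq2, dmr2)
  expect_equal(ov2$summary$overlap_pct, 31L)
  # empty DMR set: no overlap flags
  ov3 <- eqtm_dmr_overlap(eq, dmr[0])
  expect_false(any(ov3$eqtms$overlaps_dmr))
})
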