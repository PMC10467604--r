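test_that("cytosine report parsing merges strands onto the plus CpG", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("chr1\t101\t+\t5\t5",
               "chr1\t201\t+\t3\t3",
               "chr1\t202\t-\t1\t3",
               "chr2\t51\t-\t2\t0"), f)
  r <- read_cpg_report(f, "s1")
  expect_equal(r$pos, c(101L, 201L, 50L))
  expect_equal(r[pos == 101, .(meth, total)], data.table::data.table(
    meth = 5L, total = 10L))
  # hand merge: + 201 (3/6) with - 202 (1/4) -> 4/10
  expect_equal(r[pos == 201, meth], 4L)
  expect_equal(r[pos == 201, total], 10L)
  expect_equal(r[chrom == "chr2", pos], 50L)
})

test_that("degenerate and malformed reports are handled", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(), f)
  expect_warning(r <- read_cpg_report(f), "empty")
  expect_equal(nrow(r), 0L)
  writeLines(c("chr1\t101\t+\t5\t5", "chr1\t102\t?\t1\t1"), f)
  expect_error(read_cpg_report(f), "line 2")
  writeLines("chr1\t101\t+\t-5\t5", f)
  expect_error(read_cpg_report(f), "negative")
})

test_that("coverage bounds are inclusive and exclusions drop sites", {
  sites <- data.table::data.table(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chrX", "chr1"),
    pos = c(101L, 201L, 301L, 401L, 101L, 501L))
  data.table::setkey(sites, chrom, pos)
  total <- matrix(c(9L, 10L, 500L, 501L, 50L, 50L), ncol = 1)
  meth <- matrix(0L, 6, 1)
  x <- structure(list(sites = sites, meth = meth, total = total,
                      samples = "s1"), class = "cpg_counts")
  bl <- data.frame(chrom = "chr1", pos = 501L)
  f <- filter_sites(x, filter_config(snp_blacklist = bl))
  expect_false("chrX" %in% f$sites$chrom)          # sex chromosome
  expect_false(501L %in% f$sites$pos)              # blacklist
  keep <- f$total[, 1]
  expect_equal(is.na(keep), c(TRUE, FALSE, FALSE, TRUE))  # 9,10,500,501
})

test_that("100-bp tiling anchors at the genome grid and sums counts", {
  sites <- data.table::data.table(chrom = "chr1",
                                  pos = c(3L, 57L, 100L, 101L))
  data.table::setkey(sites, chrom, pos)
  total <- matrix(c(10L, 14L, 8L, 24L), ncol = 1)
  meth <- matrix(c(2L, 5L, 4L, 12L), ncol = 1)
  x <- structure(list(sites = sites, meth = meth, total = total,
                      samples = "s1"), class = "cpg_counts")
  tl <- tile_100bp(x)
  expect_equal(tl$tiles$start, c(0L, 100L))
  # CpGs at 3, 57 and 100 share tile [0,100); 101 starts [100,200)
  expect_equal(tl$tiles$n_cpgs, c(3L, 1L))
  expect_equal(tl$total[, 1], c(10L + 14L + 8L, 24L))
  expect_equal(tl$meth[, 1], c(11L, 12L))
  expect_equal(unname(meth_fraction(tl)[2, 1]), 0.5)       # 12 of 24
})

test_that("tiling conserves surviving counts and commutes with sample subsetting", {
  co <- small_cohort()
  x <- structure(list(sites = co$sites, meth = co$meth, total = co$total,
                      samples = co$samples), class = "cpg_counts")
  f <- filter_sites(x)
  tl <- tile_100bp(f)
  expect_equal(colSums(tl$total, na.rm = TRUE),
               colSums(f$total, na.rm = TRUE))
  expect_equal(colSums(tl$meth, na.rm = TRUE),
               colSums(f$meth, na.rm = TRUE))
  s <- co$samples[c(2, 11)]
  xs <- structure(list(sites = co$sites, meth = co$meth[, s],
                       total = co$total[, s], samples = s),
                  class = "cpg_counts")
  tl_sub <- tile_100bp(filter_sites(xs))
  expect_equal(tl_sub$meth, tl$meth[, s])
  expect_equal(tl_sub$total, tl$total[, s])
})

test_that("region profiles average a constant field to the constant", {
  total <- matrix(10L, 40, 2)
  meth <- matrix(7L, 40, 2)
  tl <- make_tiles(meth, total)
  reg <- data.frame(chrom = "chr1", start = 500L, end = 2500L)
  pr <- region_mean_methylation(tl, reg, flank_bp = 400L,
                                body_bins = 5L, flank_bin_bp = 200L)
  expect_true(all(abs(pr$profile - 0.7) < 1e-12, na.rm = TRUE))
  expect_equal(unname(pr$scalar), c(0.7, 0.7))
})

test_that("region scalar is the coverage-weighted tile mean", {
  total <- matrix(20L, 2, 1)
  meth <- matrix(c(4L, 16L), 2, 1)    # fractions 0.2, 0.8, equal coverage
  tl <- make_tiles(meth, total)
  reg <- data.frame(chrom = "chr1", start = 0L, end = 200L)
  pr <- region_mean_methylation(tl, reg, flank_bp = 200L, body_bins = 2L)
  expect_equal(unname(pr$scalar), 0.5)
})

test_that("region profiles are invariant to region order and show planted repeat hypomethylation", {
  co <- small_cohort()
  tl <- cohort_tiles(co)
  reps <- as.data.frame(co$annotations[["repeat"]])
  p1 <- region_mean_methylation(tl, reps)
  p2 <- region_mean_methylation(tl, reps[rev(seq_len(nrow(reps))), ])
  expect_equal(p1$profile, p2$profile)
  body <- p1$bins$zone == "body"
  imu <- rowMeans(p1$profile[body, co$groups == "IMU"], na.rm = TRUE)
  krt <- rowMeans(p1$profile[body, co$groups == "KRT"], na.rm = TRUE)
  expect_true(all(krt < imu, na.rm = TRUE))
})
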