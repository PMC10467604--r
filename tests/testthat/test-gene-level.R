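genes3 <- data.frame(
  gene = c("gPlus", "gMinus", "gOverlap"),
  chrom = c("chr1", "chr1", "chr1"),
  strand = c("+", "-", "+"),
  start = c(10000L, 30000L, 12000L),
  end = c(20000L, 40000L, 22000L),
  tss = c(10000L, 39999L, 12000L))

test_that("promoters abut the TSS strand-awarely", {
  reg <- gene_regions(genes3)
  p <- reg$promoter
  expect_equal(p[p$gene == "gPlus", c("start", "end")],
               data.table::data.table(start = 9000L, end = 10000L),
               ignore_attr = TRUE)
  expect_equal(p[p$gene == "gMinus", c("start", "end")],
               data.table::data.table(start = 40000L, end = 41000L),
               ignore_attr = TRUE)
})

test_that("DMRs are counted for every overlapping gene, split by direction", {
  dmrs <- data.table::data.table(
    chrom = "chr1",
    start = c(15000L, 15100L, 15200L, 35000L, 9500L),
    end = c(15100L, 15200L, 15300L, 35100L, 9600L),
    direction = c("hyper", "hyper", "hypo", "hypo", "hyper"),
    is_dmr = c(TRUE, TRUE, TRUE, TRUE, TRUE))
  body <- count_gene_dmrs(dmrs, genes3, "body")
  # tiles at 15000-15300 fall in both gPlus and gOverlap bodies
  expect_equal(body[body$gene == "gPlus", c(n_hyper, n_hypo)], c(2L, 1L))
  expect_equal(body[body$gene == "gOverlap", c(n_hyper, n_hypo)],
               c(2L, 1L))
  expect_equal(body[body$gene == "gMinus", c(n_hyper, n_hypo)], c(0L, 1L))
  prom <- count_gene_dmrs(dmrs, genes3, "promoter")
  expect_equal(prom[prom$gene == "gPlus", n_hyper], 1L)   # 9500-9600
})

test_that("gene DMR counts match a quadratic all-pairs oracle", {
  set.seed(43)
  genes <- data.frame(gene = paste0("g", 1:100), chrom = "chr1",
                      strand = sample(c("+", "-"), 100, TRUE),
                      start = sample(seq(0L, 500000L, 1000L), 100))
  genes$end <- genes$start + sample(2000:20000, 100, TRUE)
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  dmrs <- data.table::data.table(
    chrom = "chr1", start = sample(seq(0L, 520000L, 100L), 400))
  dmrs[, `:=`(end = start + 100L,
              direction = sample(c("hyper", "hypo"), 400, TRUE),
              is_dmr = TRUE)]
  got <- count_gene_dmrs(dmrs, genes, "body")
  for (i in sample(100, 20)) {
    sel <- dmrs$start < genes$end[i] & dmrs$end > genes$start[i]
    expect_equal(got$n_hyper[got$gene == genes$gene[i]],
                 sum(sel & dmrs$direction == "hyper"))
    expect_equal(got$n_hypo[got$gene == genes$gene[i]],
                 sum(sel & dmrs$direction == "hypo"))
  }
})

test_that("direction calls follow the count-comparison rule", {
  counts <- data.frame(gene = c("CCNA1", "CDH23", "CDH13", "tied",
                                "silent"),
                       n_hyper = c(8L, 445L, 0L, 3L, 0L),
                       n_hypo = c(0L, 0L, 233L, 3L, 0L))
  calls <- call_direction(counts, "demo")
  expect_equal(calls$direction,
               c("hyper", "hyper", "hypo", "tied", "none"))
})

test_that("direction calls are antisymmetric under contrast swap", {
  set.seed(47)
  counts <- data.frame(gene = paste0("g", 1:50),
                       n_hyper = rpois(50, 2), n_hypo = rpois(50, 2))
  a <- call_direction(counts)
  b <- call_direction(data.frame(gene = counts$gene,
                                 n_hyper = counts$n_hypo,
                                 n_hypo = counts$n_hyper))
  flip <- c(hyper = "hypo", hypo = "hyper", tied = "tied", none = "none")
  expect_equal(b$direction, unname(flip[a$direction]))
})

test_that("literature concordance classes partition the table and reproduce printed shares", {
  # 58 retained hypermethylated genes: 43 IMU-only, 15 both -> 74%
  lit <- data.frame(gene = paste0("g", 1:70), direction = "hyper")
  dir_imu <- c(rep("hyper", 58), rep("hypo", 12))
  dir_krt <- c(rep("hyper", 15), rep("none", 43), rep("hypo", 12))
  calls_imu <- data.frame(gene = lit$gene, direction = dir_imu)
  calls_krt <- data.frame(gene = lit$gene, direction = dir_krt)
  lc <- literature_concordance(calls_imu, calls_krt, lit)
  expect_equal(sum(table(lc$genes$class)), nrow(lit))
  s <- lc$summary[lc$summary$direction == "hyper", ]
  expect_equal(s$n_retained, 58L)
  expect_equal(s$n_imu_only, 43L)
  expect_equal(s$imu_only_pct, 74L)
  # promoter-level share: 31 of 47 genes hypermethylated only in IMU
  expect_equal(pct_share(31, 47), 66L)
  # empty table -> empty report
  lc0 <- literature_concordance(calls_imu, calls_krt, lit[0, ])
  expect_equal(nrow(lc0$genes), 0L)
})

test_that("cross-cohort direction cross-tabs detect reversed sites exactly", {
  set.seed(53)
  n <- 500
  a <- data.frame(chrom = "chr1", start = (0:(n - 1)) * 100,
                  end = (1:n) * 100,
                  direction = sample(c("hyper", "hypo"), n, TRUE))
  ct <- direction_crosstab(a, a)
  expect_equal(ct$reversed_frac, 0)
  expect_equal(sum(diag(ct$table)), n)
  b <- a; b$direction <- ifelse(a$direction == "hyper", "hypo", "hyper")
  ct2 <- direction_crosstab(a, b)
  expect_equal(ct2$reversed_frac, 1)
  flipped <- sample(n, 50)                   # plant 10% reversed
  c_ <- a; c_$direction[flipped] <- b$direction[flipped]
  ct3 <- direction_crosstab(a, c_)
  expect_equal(ct3$reversed_frac, 0.1)
  expect_setequal(ct3$reversed$start, a$start[flipped])
  expect_error(direction_crosstab(a, data.frame(chrom = "chr9",
                                                start = 1, end = 2,
                                                direction = "hyper")),
               "no shared")
})
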