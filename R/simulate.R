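#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions emulated by the generator: a 36-sample
#' cohort split into an immune-strong HPV(+) subtype (IMU, n = 8), a
#' keratinized HPV(+) subtype (KRT, n = 10) and HPV(-) tumors (n = 18),
#' with genome-wide mean methylation 62 / 51 / 52 per cent respectively,
#' ~24x mean CpG coverage, beta-binomial within-group dispersion, planted
#' DMR blocks, methylation-coupled expression for a subset of genes,
#' CNA segment sets with known instability scores, regulatory region
#' sets with planted methylation dips, and a cell-type methylation atlas
#' with known mixture fractions.
#'
#' @param n_chroms,chrom_len_bp Methylation genome size.
#' @param cpg_spacing_mean_bp Mean CpG spacing outside islands
#'   (exponential spacing; islands are ~5x denser hotspots).
#' @param group_sizes,group_global_meth Named per-group sample counts
#'   and target genome-wide methylation fractions.
#' @param n_dmr_blocks,dmr_effect_pp Number of planted DMR blocks and
#'   their effect in percentage points (0 disables planting).
#' @param mean_coverage,coverage_dispersion Negative-binomial per-CpG
#'   coverage model (mean, size).
#' @param beta_dispersion_phi Within-group beta-binomial dispersion.
#' @param n_genes,n_eqtm_genes,eqtm_slope,eqtm_noise_sd Gene models and
#'   the planted cis-eQTM structure (expression units per methylation
#'   fraction unit; Gaussian noise SD on log2-CPM).
#' @param n_regset_regions Regions per regulatory region set.
#' @param group_instability Named mean instability score per group.
#' @param n_cna_decoys Named per-group count of non-contributing decoy
#'   CNA segments (neutral or sub-10 Mb).
#' @param n_atlas_regions,tumor_purity Deconvolution fixture size and
#'   named per-group mean tumor purity.
#' @param confounded_covariates If `TRUE`, covariates co-vary with
#'   subtype (robustness testing); default independent.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_chroms = 2L, chrom_len_bp = 400000L,
                       cpg_spacing_mean_bp = 60,
                       group_sizes = c(IMU = 8L, KRT = 10L, HPVneg = 18L),
                       group_global_meth = c(IMU = 0.62, KRT = 0.51,
                                             HPVneg = 0.52),
                       n_dmr_blocks = 60L, dmr_effect_pp = 30,
                       mean_coverage = 24, coverage_dispersion = 8,
                       beta_dispersion_phi = 0.1,
                       n_genes = 60L, n_eqtm_genes = 25L,
                       n_regset_regions = 60L,
                       eqtm_slope = -2, eqtm_noise_sd = 0.5,
                       group_instability = c(IMU = 40.5, KRT = 54.8,
                                             HPVneg = 82.4),
                       n_cna_decoys = c(IMU = 6L, KRT = 8L, HPVneg = 10L),
                       n_atlas_regions = 500L,
                       tumor_purity = c(IMU = 0.50, KRT = 0.65,
                                        HPVneg = 0.60),
                       confounded_covariates = FALSE,
                       seed = 1L) {
  stop_if(any(group_global_meth < 0 | group_global_meth > 1),
          "group_global_meth must lie in [0, 1]")
  stop_if(any(group_sizes < 1) || n_chroms < 1 || chrom_len_bp < 1,
          "all counts must be >= 1")
  stop_if(!setequal(names(group_sizes), names(group_global_meth)),
          "group name mismatch")
  stop_if(beta_dispersion_phi <= 0 || beta_dispersion_phi >= 1,
          "beta_dispersion_phi must be in (0, 1)")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# shift site means additively (then clip) so their average hits `target`
calibrate_shift <- function(base, target) {
  f <- function(d) mean(clip01(base + d, 0.01, 0.99)) - target
  stats::uniroot(f, c(-1, 1), tol = 1e-10)$root
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Simulate a full synthetic tumor methylome cohort
#'
#' Generates everything the pipeline consumes, with ground truth:
#' per-sample cytosine reports (both strands), sample metadata,
#' gene models, annotation BEDs (promoter/exon/intron, CpG
#' island/shore/shelf, repeat families), a log2-CPM expression matrix
#' with planted cis-eQTM genes and subtype-structured pathway gene sets,
#' CNA segments on an arm-annotated genome with known instability
#' scores anticorrelated with methylation, regulatory region sets with
#' planted group-specific methylation dips, and a cell-type atlas with
#' known mixture fractions and tumor methylomes.
#'
#' Methylated counts are beta-binomial: coverage is negative-binomial,
#' the per-site, per-sample success probability is Beta-distributed
#' around the group/site mean with intraclass dispersion
#' `beta_dispersion_phi`. Planted DMR blocks shift one group's site
#' means by `dmr_effect_pp`; shifts pushed outside [0, 1] are clipped
#' and counted in the ground truth.
#'
#' @param cfg A [sim_config()].
#' @return A `sim_cohort` bundle (lists of data.tables/matrices) with a
#'   `ground_truth` element; see [write_cohort()] to materialise it as
#'   files.
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  groups <- rep(names(cfg$group_sizes), cfg$group_sizes)
  samples <- paste0(groups, ave(seq_along(groups), groups, FUN = seq_along))
  ns <- length(samples)
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  chrom_sizes <- stats::setNames(rep(cfg$chrom_len_bp, cfg$n_chroms), chroms)

  ## --- CpG landscape: exponential spacing with island hotspots -------
  pos_list <- list(); isl_list <- list()
  for (ch in chroms) {
    L <- cfg$chrom_len_bp
    centers <- seq(12000, L - 12000, by = 25000)
    widths <- round(runif(length(centers), 500, 1200))
    isl <- data.table::data.table(chrom = ch,
                                  start = pmax(0, centers - widths %/% 2),
                                  end = pmin(L, centers + widths %/% 2))
    sea <- cumsum(stats::rexp(ceiling(2.2 * L / cfg$cpg_spacing_mean_bp),
                              1 / cfg$cpg_spacing_mean_bp)) + 1
    sea <- sea[sea < L - 1]
    dense <- unlist(lapply(seq_len(nrow(isl)), function(i) {
      p <- cumsum(stats::rexp(ceiling((isl$end[i] - isl$start[i]) / 6),
                              1 / (cfg$cpg_spacing_mean_bp / 5)))
      isl$start[i] + p[p < isl$end[i] - isl$start[i]]
    }))
    pos <- sort(unique(as.integer(c(sea, dense))))
    pos <- pos[pos >= 2 & pos < L]
    pos_list[[ch]] <- data.table::data.table(chrom = ch, pos = pos)
    isl_list[[ch]] <- isl
  }
  sites <- data.table::rbindlist(pos_list)
  islands <- data.table::rbindlist(isl_list)
  n_sites <- nrow(sites)
  in_island <- overlaps_point(sites, islands)
  in_shore <- overlaps_point(sites, flank_bed(islands, 2000, chrom_sizes)) &
    !in_island

  ## --- baseline and per-group site means ----------------------------
  base <- numeric(n_sites)
  base[in_island] <- rbeta(sum(in_island), 1.2, 8.8)        # mean 0.12
  base[in_shore] <- rbeta(sum(in_shore), 5, 5)              # mean 0.50
  rest <- !(in_island | in_shore)
  base[rest] <- rbeta(sum(rest), 8.2, 1.8)                  # mean 0.82

  ## --- gene models and annotations ----------------------------------
  genes <- simulate_genes(cfg, chroms, chrom_sizes)
  annotations <- build_annotations(genes, islands, chrom_sizes, cfg)

  # extra repeat hypomethylation in KRT / HPV(-): transposable-element
  # demethylation tracks global instability in the keratinized arm;
  # folded into the calibration so group means still hit their targets
  rep_bed <- annotations[["repeat"]]
  in_rep <- overlaps_point(sites, rep_bed)
  rep_delta <- c(IMU = 0, KRT = -0.05, HPVneg = -0.04)
  group_mean <- sapply(names(cfg$group_sizes), function(g) {
    bg <- base + rep_delta[[g]] * in_rep
    clip01(bg + calibrate_shift(bg, cfg$group_global_meth[[g]]),
           0.01, 0.99)
  })  # sites x groups

  ## --- planted DMR blocks -------------------------------------------
  clip_events <- 0L
  planted <- data.table::data.table()
  if (cfg$n_dmr_blocks > 0 && cfg$dmr_effect_pp > 0) {
    e <- cfg$dmr_effect_pp / 100
    types <- sample(c("IMU_up", "KRT_down", "HPVneg_down"),
                    cfg$n_dmr_blocks, replace = TRUE,
                    prob = c(0.5, 0.3, 0.2))
    blk <- data.table::data.table(
      chrom = sample(chroms, cfg$n_dmr_blocks, replace = TRUE),
      start = sample(seq(0, cfg$chrom_len_bp - 400, by = 100),
                     cfg$n_dmr_blocks),
      width = 100L * sample(1:3, cfg$n_dmr_blocks, replace = TRUE),
      type = types)
    blk[, end := start + width]
    rows <- list()
    for (i in seq_len(nrow(blk))) {
      sel <- sites$chrom == blk$chrom[i] & sites$pos > blk$start[i] &
        sites$pos <= blk$end[i]
      if (!any(sel)) next
      g <- switch(blk$type[i], IMU_up = "IMU", KRT_down = "KRT",
                  HPVneg_down = "HPVneg")
      sgn <- if (blk$type[i] == "IMU_up") 1 else -1
      shifted <- group_mean[sel, g] + sgn * e
      clip_events <- clip_events + sum(shifted < 0.01 | shifted > 0.99)
      group_mean[sel, g] <- clip01(shifted, 0.01, 0.99)
      others <- setdiff(names(cfg$group_sizes), g)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        chrom = blk$chrom[i], start = blk$start[i], end = blk$end[i],
        groupA = g, groupB = others,
        effect_pp = sgn * cfg$dmr_effect_pp)
    }
    planted <- data.table::rbindlist(rows)
    if (clip_events > 0)
      warning(clip_events, " planted site means clipped to [0.01, 0.99]")
  }

  ## --- variably methylated tiles coupled to expression (eQTMs) ------
  # planted eQTM tiles are VMR-like: per-sample tile methylation drawn
  # Beta(2, 2), the bimodal-to-intermediate spread typical of
  # regulatory regions that differ across tumors
  site_mean <- group_mean[, groups, drop = FALSE]  # sites x samples
  colnames(site_mean) <- samples
  eqtm_genes <- sample(genes$gene, min(cfg$n_eqtm_genes, nrow(genes)))
  planted_eqtms <- data.table::data.table()
  if (length(eqtm_genes) > 0 && cfg$eqtm_slope != 0) {
    rows <- list()
    for (g in eqtm_genes) {
      gi <- which(genes$gene == g)
      tss <- genes$tss[gi]
      tile_start <- (pmax(0, tss + sample(c(-1, 1), 1) *
                            sample(2000:20000, 1)) %/% 100) * 100
      sel <- which(sites$chrom == genes$chrom[gi] &
                     sites$pos > tile_start & sites$pos <= tile_start + 100)
      if (length(sel) == 0) next
      mv <- rbeta(ns, 2, 2)
      site_mean[sel, ] <- matrix(rep(mv, each = length(sel)),
                                 nrow = length(sel))
      rows[[length(rows) + 1L]] <- data.table::data.table(
        chrom = genes$chrom[gi], start = tile_start,
        end = tile_start + 100L, gene = g,
        slope = cfg$eqtm_slope, tile_meth = list(mv))
    }
    planted_eqtms <- data.table::rbindlist(rows)
  }

  ## --- regulatory region sets with planted dips ---------------------
  dip_center <- list(TFBS_A = c(IMU = 0.45, KRT = 0.22, HPVneg = 0.25),
                     enhancer = c(IMU = 0.50, KRT = 0.28, HPVneg = 0.30))
  region_sets <- list()
  for (rs in names(dip_center)) {
    nr <- cfg$n_regset_regions
    centers <- data.table::data.table(
      chrom = sample(chroms, nr, replace = TRUE),
      center = sample(seq(20000L, cfg$chrom_len_bp - 20000L), nr))
    region_sets[[rs]] <- data.table::data.table(
      chrom = centers$chrom, start = centers$center - 100L,
      end = centers$center + 100L,
      name = paste0(rs, "_", seq_len(nr)), score = 0L, strand = "+")
    for (i in seq_len(nr)) {
      sel <- which(sites$chrom == centers$chrom[i] &
                     abs(sites$pos - centers$center[i]) <= 150)
      if (length(sel) == 0) next
      kern <- exp(-((sites$pos[sel] - centers$center[i])^2) / (2 * 80^2))
      for (g in names(cfg$group_sizes)) {
        cols <- which(groups == g)
        tgt <- dip_center[[rs]][[g]]
        site_mean[sel, cols] <- site_mean[sel, cols] * (1 - kern) +
          tgt * kern
      }
    }
  }

  ## --- counts: NB coverage, beta-binomial methylation ---------------
  size_factor <- exp(rnorm(ns, 0, 0.15))
  phi <- cfg$beta_dispersion_phi
  conc <- (1 - phi) / phi
  total <- matrix(0L, n_sites, ns, dimnames = list(NULL, samples))
  meth <- total
  for (j in seq_len(ns)) {
    t_j <- rnbinom(n_sites, mu = cfg$mean_coverage * size_factor[j],
                   size = cfg$coverage_dispersion)
    p_j <- rbeta(n_sites, site_mean[, j] * conc,
                 (1 - site_mean[, j]) * conc)
    total[, j] <- t_j
    meth[, j] <- rbinom(n_sites, t_j, p_j)
  }

  ## --- metadata ------------------------------------------------------
  hpv_pos <- groups %in% c("IMU", "KRT")
  p_smoke <- if (cfg$confounded_covariates)
    ifelse(groups == "HPVneg", 0.8, 0.3) else rep(0.5, ns)
  metadata <- data.table::data.table(
    sample = samples, subtype = groups,
    hpv_status = ifelse(hpv_pos, "HPVpos", "HPVneg"),
    hpv_integration = ifelse(hpv_pos & runif(ns) < 0.5,
                             "HPVint_pos", "HPVint_neg"),
    sex = sample(c("M", "F"), ns, replace = TRUE),
    age = round(rnorm(ns, 60, 8)),
    smoking = ifelse(runif(ns) < p_smoke, "smoker", "never"),
    stage = sample(c("IV", "other"), ns, replace = TRUE,
                   prob = c(0.4, 0.6)),
    hpv_cpm = ifelse(hpv_pos, round(exp(rnorm(ns, 4, 1)), 2), 0))

  ## --- expression ----------------------------------------------------
  expr_out <- simulate_expression(cfg, genes, metadata, planted_eqtms,
                                  samples, groups)

  ## --- CNA segments with known instability --------------------------
  sample_meth_mean <- colMeans(site_mean)
  cna <- simulate_cna(cfg, metadata, sample_meth_mean)

  ## --- atlas + mixtures for deconvolution ---------------------------
  deco <- simulate_atlas(cfg, chroms, chrom_sizes, groups, samples)

  ground_truth <- list(
    planted_dmrs = planted, planted_eqtms = planted_eqtms,
    clip_events = clip_events,
    true_instability = cna$true_instability,
    true_cell_fractions = deco$true_fractions,
    tumor_meth_mean = deco$tumor_meth_mean,
    dip_center = dip_center,
    group_sizes = cfg$group_sizes,
    sample_meth_mean = sample_meth_mean,
    gene_sets = expr_out$gene_sets)

  structure(list(
    cfg = cfg, samples = samples, groups = groups, chroms = chroms,
    chrom_sizes = chrom_sizes,
    sites = sites, meth = meth, total = total, site_mean = site_mean,
    metadata = metadata, genes = genes, annotations = annotations,
    islands = islands, expression = expr_out$expression,
    gene_sets = expr_out$gene_sets,
    cna_seg = cna$seg, arms = cna$arms,
    region_sets = region_sets,
    atlas = deco$atlas, atlas_regions = deco$regions,
    mixture_meth = deco$mixture_meth,
    ground_truth = ground_truth),
    class = "sim_cohort")
}

#' Simulate beta-binomial tile counts directly
#'
#' Bypasses the genome layer: draws per-tile, per-sample methylation
#' counts for a two-group design, optionally planting an effect in the
#' first `n_planted` tiles. Used for calibration and power studies of
#' the differential test under known dispersion.
#'
#' @param n_tiles Number of tiles.
#' @param n_a,n_b Group sizes.
#' @param coverage Mean per-tile coverage (negative binomial, size 8).
#' @param phi Beta-binomial dispersion.
#' @param effect_pp Planted group-A shift, percentage points.
#' @param n_planted Number of leading tiles carrying the effect.
#' @param base_mean Optional fixed baseline mean; by default tile
#'   baselines are drawn from the genome-like mixture (20% Beta(1.2,
#'   8.8) island-like, 80% Beta(8.2, 1.8) open-sea-like), truncated to
#'   [0.05, 0.95 - effect] for planted tiles.
#' @param seed Integer seed.
#' @return A `meth_tiles` object (synthetic coordinates) with attribute
#'   `planted` (logical vector).
#' @export
simulate_tile_counts <- function(n_tiles, n_a = 8L, n_b = 10L,
                                 coverage = 24, phi = 0.1,
                                 effect_pp = 0, n_planted = 0L,
                                 base_mean = NULL, seed = 1L) {
  set.seed(seed)
  ns <- n_a + n_b
  samples <- c(paste0("A", seq_len(n_a)), paste0("B", seq_len(n_b)))
  isl <- runif(n_tiles) < 0.2
  base <- base_mean %||% ifelse(isl, rbeta(n_tiles, 1.2, 8.8),
                                rbeta(n_tiles, 8.2, 1.8))
  base <- clip01(base, 0.05, 0.95)
  planted <- seq_len(n_tiles) <= n_planted
  base[planted] <- clip01(base[planted], 0.05, 0.95 - effect_pp / 100)
  mean_a <- base + planted * effect_pp / 100
  conc <- (1 - phi) / phi
  total <- matrix(rnbinom(n_tiles * ns, mu = coverage, size = 8),
                  n_tiles, ns, dimnames = list(NULL, samples))
  total[total == 0] <- 1L
  mu <- cbind(matrix(mean_a, n_tiles, n_a), matrix(base, n_tiles, n_b))
  p <- matrix(rbeta(n_tiles * ns, mu * conc, (1 - mu) * conc),
              n_tiles, ns)
  meth <- matrix(rbinom(n_tiles * ns, total, p), n_tiles, ns,
                 dimnames = list(NULL, samples))
  out <- structure(list(
    tiles = data.table::data.table(chrom = "chrS",
                                   start = (seq_len(n_tiles) - 1L) * 100L,
                                   end = seq_len(n_tiles) * 100L,
                                   n_cpgs = 1L),
    meth = meth, total = total, samples = samples),
    class = "meth_tiles")
  attr(out, "planted") <- planted
  attr(out, "design") <- structure(
    list(samplesA = samples[seq_len(n_a)],
         samplesB = samples[n_a + seq_len(n_b)],
         covariates = NULL, contrast = "A_vs_B"),
    class = "group_design")
  out
}

overlaps_point <- function(sites, bed) {
  hit <- rep(FALSE, nrow(sites))
  for (i in seq_len(nrow(bed))) {
    hit <- hit | (sites$chrom == bed$chrom[i] & sites$pos > bed$start[i] &
                    sites$pos <= bed$end[i])
  }
  hit
}

flank_bed <- function(bed, fl, chrom_sizes) {
  data.table::data.table(chrom = bed$chrom,
                         start = pmax(0, bed$start - fl),
                         end = pmin(chrom_sizes[bed$chrom], bed$end + fl))
}

simulate_genes <- function(cfg, chroms, chrom_sizes) {
  per <- ceiling(cfg$n_genes / length(chroms))
  rows <- list()
  for (ch in chroms) {
    slots <- seq(5000, cfg$chrom_len_bp - 35000,
                 length.out = per)
    for (i in seq_len(per)) {
      len <- sample(5000:25000, 1)
      start <- as.integer(slots[i])
      strand <- sample(c("+", "-"), 1)
      rows[[length(rows) + 1L]] <- data.table::data.table(
        gene = sprintf("G%s_%02d", sub("chr", "", ch), i),
        chrom = ch, strand = strand, start = start,
        end = start + len,
        tss = if (strand == "+") start else start + len - 1L)
    }
  }
  data.table::rbindlist(rows)[seq_len(cfg$n_genes)]
}

build_annotations <- function(genes, islands, chrom_sizes, cfg) {
  prom <- data.table::data.table(
    chrom = genes$chrom,
    start = ifelse(genes$strand == "+", pmax(0, genes$tss - 1000L),
                   genes$tss + 1L),
    end = ifelse(genes$strand == "+", genes$tss,
                 genes$tss + 1001L),
    name = genes$gene, score = 0L, strand = genes$strand)
  exon <- list(); intron <- list()
  for (i in seq_len(nrow(genes))) {
    nex <- sample(3:6, 1)
    bounds <- sort(sample(seq(genes$start[i], genes$end[i], by = 50),
                          2 * nex))
    st <- bounds[seq(1, 2 * nex, 2)]; en <- bounds[seq(2, 2 * nex, 2)]
    exon[[i]] <- data.table::data.table(chrom = genes$chrom[i],
                                        start = st, end = en,
                                        name = genes$gene[i],
                                        score = 0L,
                                        strand = genes$strand[i])
    if (nex > 1)
      intron[[i]] <- data.table::data.table(chrom = genes$chrom[i],
                                            start = en[-nex],
                                            end = st[-1],
                                            name = genes$gene[i],
                                            score = 0L,
                                            strand = genes$strand[i])
  }
  shore <- flank_bed(islands, 2000, chrom_sizes)
  shelf <- data.table::data.table(
    chrom = rep(islands$chrom, 2),
    start = c(pmax(0, islands$start - 4000), islands$end + 2000),
    end = c(pmax(0, islands$start - 2000),
            pmin(chrom_sizes[islands$chrom], islands$end + 4000)))
  fam <- c("LINE1", "LINE2", "Alu")
  nrep <- max(20L, as.integer(round(cfg$n_chroms * cfg$chrom_len_bp / 1e4)))
  reps <- data.table::data.table(
    chrom = sample(names(chrom_sizes), nrep, replace = TRUE),
    start = sample(seq(0L, cfg$chrom_len_bp - 7000L), nrep),
    width = sample(300:6000, nrep, replace = TRUE),
    family = sample(fam, nrep, replace = TRUE, prob = c(0.4, 0.2, 0.4)))
  reps[, `:=`(end = start + width, name = family, score = 0L,
              strand = "+")]
  list(promoter = prom,
       exon = data.table::rbindlist(exon),
       intron = data.table::rbindlist(intron),
       cpg_island = data.table::data.table(islands, name = "island",
                                           score = 0L, strand = "+"),
       shore = data.table::data.table(shore, name = "shore", score = 0L,
                                      strand = "+"),
       shelf = data.table::data.table(shelf, name = "shelf", score = 0L,
                                      strand = "+"),
       `repeat` = reps[, .(chrom, start, end, name, score, strand)])
}

simulate_expression <- function(cfg, genes, metadata, planted_eqtms,
                                samples, groups) {
  ns <- length(samples)
  ng <- nrow(genes)
  base <- rnorm(ng, 5, 1.5)
  expr <- matrix(base, ng, ns) + matrix(rnorm(ng * ns, 0, 0.4), ng, ns)
  dimnames(expr) <- list(genes$gene, samples)
  # pathway gene sets with subtype structure: keratinization high in
  # KRT/HPV(-), T-cell and EMT programmes high in IMU
  free <- setdiff(genes$gene, planted_eqtms$gene)
  if (length(free) < 6) free <- genes$gene   # tiny configs: allow reuse
  set_size <- max(2L, min(6L, length(free) %/% 3L))
  sets <- list()
  take <- function(n) {
    g <- utils::head(free, n); free <<- setdiff(free, g); g
  }
  sets$keratinization <- take(set_size)
  sets$t_cell <- take(set_size)
  sets$emt <- take(set_size)
  expr[sets$keratinization, groups != "IMU"] <-
    expr[sets$keratinization, groups != "IMU"] + 1.5
  expr[sets$t_cell, groups == "IMU"] <-
    expr[sets$t_cell, groups == "IMU"] + 1.5
  expr[sets$emt, groups == "IMU"] <- expr[sets$emt, groups == "IMU"] + 1.2
  # covariate effects on all genes (mild, so the eQTM covariate
  # adjustment has something real to absorb)
  age_c <- metadata$age - mean(metadata$age)
  smoke <- as.numeric(metadata$smoking == "smoker")
  expr <- expr + outer(rnorm(ng, 0, 0.01), age_c) +
    outer(rnorm(ng, 0, 0.2), smoke)
  if (nrow(planted_eqtms) > 0) {
    for (i in seq_len(nrow(planted_eqtms))) {
      g <- planted_eqtms$gene[i]
      mv <- planted_eqtms$tile_meth[[i]]
      expr[g, ] <- base[match(g, genes$gene)] +
        planted_eqtms$slope[i] * mv +
        0.01 * age_c + 0.2 * smoke + rnorm(ns, 0, cfg$eqtm_noise_sd)
    }
  }
  list(expression = round(expr, 4), gene_sets = sets)
}

simulate_cna <- function(cfg, metadata, sample_meth_mean) {
  n_cna_chrom <- 16L
  cna_len <- 240e6
  arm_rows <- list()
  for (i in seq_len(n_cna_chrom)) {
    arm_rows[[i]] <- data.table::data.table(
      chrom = paste0("chr", i),
      start = c(0, 130e6), end = c(110e6, cna_len),
      name = paste0(i, c("p", "q")), score = 0L, strand = "+")
  }
  arms <- data.table::rbindlist(arm_rows)
  groups <- metadata$subtype
  gm <- tapply(sample_meth_mean, groups, mean)
  seg_rows <- list()
  true_inst <- stats::setNames(numeric(nrow(metadata)), metadata$sample)
  for (j in seq_len(nrow(metadata))) {
    g <- groups[j]
    t_j <- max(0, round(cfg$group_instability[[g]] -
                          300 * (sample_meth_mean[j] - gm[[g]]) +
                          rnorm(1, 0, 8)))
    true_inst[j] <- t_j
    n2 <- min(t_j %/% 2, 8L)          # arm-level |CN-2| = 2 events
    rem <- t_j - 2L * n2
    n1a <- min(rem, 4L)               # arm-level |CN-2| = 1 events
    nf <- rem - n1a                   # focal (>10 Mb) binary events
    arm_idx <- sample(nrow(arms))
    used <- n2 + n1a
    segs <- list()
    add_arm <- function(k, cn) {
      a <- arms[arm_idx[k]]
      data.table::data.table(sample = metadata$sample[j], chrom = a$chrom,
                             start = a$start, end = a$end,
                             copy_number = cn)
    }
    for (k in seq_len(n2)) segs[[length(segs) + 1L]] <-
      add_arm(k, sample(c(0, 4), 1))
    for (k in seq_len(n1a)) segs[[length(segs) + 1L]] <-
      add_arm(n2 + k, sample(c(1, 3), 1))
    free_arms <- arms[arm_idx[seq(used + 1L, nrow(arms))]]
    fa <- 1L; off <- 0
    for (k in seq_len(nf)) {
      a <- free_arms[fa]
      st <- a$start + off
      if (st + 16e6 > a$end) {
        fa <- fa + 1L
        stop_if(fa > nrow(free_arms), "focal CNA capacity exceeded")
        off <- 0; a <- free_arms[fa]; st <- a$start
      }
      segs[[length(segs) + 1L]] <- data.table::data.table(
        sample = metadata$sample[j], chrom = a$chrom, start = st,
        end = st + sample(11:15, 1) * 1e6, copy_number = sample(c(1, 3), 1))
      off <- segs[[length(segs)]]$end - a$start + 1e6
    }
    nd <- cfg$n_cna_decoys[[g]]
    for (k in seq_len(nd)) {
      a <- arms[sample(nrow(arms), 1)]
      st <- a$start + sample(0:80, 1) * 1e6
      w <- if (runif(1) < 0.5) sample(2:9, 1) * 1e6 else 15e6
      cn <- if (w > 10e6) 2 else sample(c(0, 1, 3, 4), 1)
      segs[[length(segs) + 1L]] <- data.table::data.table(
        sample = metadata$sample[j], chrom = a$chrom, start = st,
        end = min(st + w, a$end), copy_number = cn)
    }
    seg_rows[[j]] <- data.table::rbindlist(segs)
  }
  list(seg = data.table::rbindlist(seg_rows), arms = arms,
       true_instability = true_inst)
}

simulate_atlas <- function(cfg, chroms, chrom_sizes, groups, samples) {
  ns <- length(samples)
  nr <- cfg$n_atlas_regions
  cell_types <- c("epithelial", "fibroblast", "tcell", "bcell",
                  "myeloid", "endothelial")
  regions <- data.table::data.table(
    chrom = sample(chroms, nr, replace = TRUE),
    start = sample(seq(0L, min(chrom_sizes) - 200L, by = 100L), nr,
                   replace = TRUE))
  regions[, end := start + 100L]
  regions[, id := paste0(chrom, ":", start, "-", end)]
  baseline <- rbeta(nr, 7, 3)                       # mean ~0.7
  atlas <- matrix(rep(baseline, each = length(cell_types)),
                  nrow = length(cell_types),
                  dimnames = list(cell_types, regions$id))
  atlas <- clip01(atlas + matrix(rnorm(length(atlas), 0, 0.03),
                                 nrow = length(cell_types)), 0.02, 0.98)
  # cell-type-specific hypomethylated markers (~55 regions per type)
  owner <- sample(rep(c(cell_types, NA), length.out = nr))
  for (ct in cell_types) {
    atlas[ct, which(owner == ct)] <- runif(sum(owner == ct, na.rm = TRUE),
                                           0.03, 0.15)
  }
  # tumor methylome: epithelial-derived with group-level global
  # hypomethylation so cancer-specific means track the subtype means
  epi <- atlas["epithelial", ]
  d_g <- cfg$group_global_meth - mean(epi)
  tumor <- matrix(0, nr, ns, dimnames = list(regions$id, samples))
  for (j in seq_len(ns)) {
    tumor[, j] <- clip01(epi + d_g[[groups[j]]] + rnorm(nr, 0, 0.05),
                         0.01, 0.99)
  }
  # mixture fractions: tumor purity by subtype, immune-rich IMU
  frac <- matrix(0, ns, length(cell_types) + 1,
                 dimnames = list(samples, c(cell_types, "tumor")))
  for (j in seq_len(ns)) {
    wt <- clip01(rnorm(1, cfg$tumor_purity[[groups[j]]], 0.06), 0.2, 0.9)
    # non-tumor epithelium is a minor compartment in tumor tissue;
    # stroma and immune infiltrate dominate the normal fraction
    alpha <- c(epithelial = 0.25, fibroblast = 2, tcell = 1, bcell = 1,
               myeloid = 1, endothelial = 1)
    if (groups[j] == "IMU") alpha[c("tcell", "bcell", "myeloid")] <- 4
    frac[j, cell_types] <- (1 - wt) * rdirichlet1(alpha)
    frac[j, "tumor"] <- wt
  }
  mixture <- t(atlas) %*% t(frac[, cell_types, drop = FALSE]) +
    tumor * matrix(rep(frac[, "tumor"], each = nr), nr)
  mixture <- clip01(mixture + matrix(rnorm(nr * ns, 0, 0.03), nr), 0, 1)
  list(atlas = atlas, regions = regions, mixture_meth = mixture,
       true_fractions = frac,
       tumor_meth_mean = stats::setNames(colMeans(tumor), samples))
}
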