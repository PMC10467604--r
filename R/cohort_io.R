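#' Write a simulated cohort to disk
#'
#' Materialises a [simulate_cohort()] bundle in the formats the
#' pipeline reads: Bismark-style cytosine reports (one TSV per sample,
#' both strands, no header), metadata/gene-model/expression TSVs, BED6
#' annotation and region-set files, a SEG-like CNA table, an arm BED,
#' the atlas and mixture matrices, and the ground truth as JSON.
#' Output is deterministic: rewriting the same bundle gives
#' byte-identical files.
#'
#' @param cohort A `sim_cohort` bundle.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(file.path(dir, "reports"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(dir, "beds"), showWarnings = FALSE)
  paths <- c()
  ## cytosine reports: split each CpG's counts onto the two strands
  for (j in seq_along(cohort$samples)) {
    s <- cohort$samples[j]
    t_all <- cohort$total[, j]; m_all <- cohort$meth[, j]
    t_plus <- rbinom_det(t_all, j)
    m_plus <- rhyper_det(m_all, t_all, t_plus, j)
    rep_dt <- data.table::data.table(
      chrom = rep(cohort$sites$chrom, 2),
      pos = c(cohort$sites$pos, cohort$sites$pos + 1L),
      strand = rep(c("+", "-"), each = nrow(cohort$sites)),
      meth = c(m_plus, m_all - m_plus),
      unmeth = c(t_plus - m_plus, (t_all - t_plus) - (m_all - m_plus)))
    data.table::setorder(rep_dt, chrom, pos, strand)
    p <- file.path(dir, "reports", paste0(s, ".cytosine_report.txt"))
    write_tsv0(rep_dt, p, col.names = FALSE)
    paths[paste0("report_", s)] <- p
  }
  paths["metadata"] <- write_tsv0(cohort$metadata,
                                  file.path(dir, "metadata.tsv"))
  paths["gene_models"] <- write_tsv0(cohort$genes,
                                     file.path(dir, "gene_models.tsv"))
  for (nm in names(cohort$annotations)) {
    p <- file.path(dir, "beds", paste0("annotation_", nm, ".bed"))
    write_tsv0(cohort$annotations[[nm]], p, col.names = FALSE)
    paths[paste0("annotation_", nm)] <- p
  }
  for (nm in names(cohort$region_sets)) {
    p <- file.path(dir, "beds", paste0("regionset_", nm, ".bed"))
    write_tsv0(cohort$region_sets[[nm]], p, col.names = FALSE)
    paths[paste0("regionset_", nm)] <- p
  }
  expr <- data.table::data.table(gene = rownames(cohort$expression),
                                 cohort$expression)
  paths["expression"] <- write_tsv0(expr, file.path(dir, "expression.tsv"))
  paths["cna_seg"] <- write_tsv0(cohort$cna_seg,
                                 file.path(dir, "cna.seg"))
  paths["arms"] <- write_tsv0(cohort$arms[, .(chrom, start, end, name)],
                              file.path(dir, "arms.bed"),
                              col.names = FALSE)
  atl <- data.table::data.table(region = colnames(cohort$atlas),
                                t(cohort$atlas))
  paths["atlas"] <- write_tsv0(atl, file.path(dir, "atlas.tsv"))
  mix <- data.table::data.table(region = rownames(cohort$mixture_meth),
                                round(cohort$mixture_meth, 5))
  paths["mixture_meth"] <- write_tsv0(mix,
                                      file.path(dir, "mixture_meth.tsv"))
  sizes <- data.table::data.table(chrom = names(cohort$chrom_sizes),
                                  size = as.integer(cohort$chrom_sizes))
  paths["chrom_sizes"] <- write_tsv0(sizes,
                                     file.path(dir, "genome.chrom.sizes"),
                                     col.names = FALSE)
  gs <- data.table::rbindlist(lapply(names(cohort$gene_sets), function(n)
    data.table::data.table(set = n, gene = cohort$gene_sets[[n]])))
  paths["gene_sets"] <- write_tsv0(gs, file.path(dir, "gene_sets.tsv"))
  gt <- cohort$ground_truth
  gt$planted_eqtms <- gt$planted_eqtms[, setdiff(names(gt$planted_eqtms),
                                                 "tile_meth"),
                                       with = FALSE]
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = 8, pretty = TRUE)
  paths["ground_truth"] <- file.path(dir, "ground_truth.json")
  invisible(paths)
}

# deterministic strand splits derived from counts (not the RNG stream),
# so writing is a pure function of the bundle
rbinom_det <- function(t_all, salt) {
  u <- det_unif(seq_along(t_all) * 13 + salt * 7)
  stats::qbinom(u, t_all, 0.5)
}

rhyper_det <- function(m, t_all, t_plus, salt) {
  u <- det_unif(seq_along(m) * 29 + salt * 3)
  stats::qhyper(u, m, t_all - m, t_plus)
}

det_unif <- function(i) {
  x <- sin(i * 12.9898 + 78.233) * 43758.5453
  x - floor(x)
}

#' Read cohort tables written by [write_cohort()]
#'
#' @param dir Cohort directory.
#' @return Named list: `metadata`, `genes`, `expression` (matrix),
#'   `annotations`, `region_sets`, `cna_seg`, `arms`, `atlas` (cell
#'   types x regions matrix), `mixture_meth` (regions x samples
#'   matrix), `chrom_sizes`, `gene_sets`, `report_paths`.
#' @export
read_cohort <- function(dir) {
  md <- data.table::fread(file.path(dir, "metadata.tsv"))
  genes <- data.table::fread(file.path(dir, "gene_models.tsv"))
  expr <- NULL
  if (file.exists(file.path(dir, "expression.tsv"))) {
    expr_dt <- data.table::fread(file.path(dir, "expression.tsv"))
    expr <- as.matrix(expr_dt[, -1]); rownames(expr) <- expr_dt$gene
  }
  beds <- list.files(file.path(dir, "beds"), full.names = TRUE)
  read_bed <- function(p) {
    b <- data.table::fread(p, header = FALSE)
    data.table::setnames(b, seq_len(min(6, ncol(b))),
                         c("chrom", "start", "end", "name", "score",
                           "strand")[seq_len(min(6, ncol(b)))])
    b
  }
  ann <- beds[grepl("annotation_", beds)]
  annotations <- stats::setNames(lapply(ann, read_bed),
                                 sub(".*annotation_(.*)\\.bed", "\\1", ann))
  rs <- beds[grepl("regionset_", beds)]
  region_sets <- stats::setNames(lapply(rs, read_bed),
                                 sub(".*regionset_(.*)\\.bed", "\\1", rs))
  atl_dt <- data.table::fread(file.path(dir, "atlas.tsv"))
  atlas <- t(as.matrix(atl_dt[, -1])); colnames(atlas) <- atl_dt$region
  mix_dt <- data.table::fread(file.path(dir, "mixture_meth.tsv"))
  mixture <- as.matrix(mix_dt[, -1]); rownames(mixture) <- mix_dt$region
  sizes <- data.table::fread(file.path(dir, "genome.chrom.sizes"),
                             header = FALSE,
                             col.names = c("chrom", "size"))
  gene_sets_dt <- data.table::fread(file.path(dir, "gene_sets.tsv"))
  gene_sets <- split(gene_sets_dt$gene, gene_sets_dt$set)
  reports <- list.files(file.path(dir, "reports"), full.names = TRUE)
  names(reports) <- sub("\\.cytosine_report\\.txt$", "", basename(reports))
  list(metadata = md, genes = genes, expression = expr,
       annotations = annotations, region_sets = region_sets,
       cna_seg = data.table::fread(file.path(dir, "cna.seg")),
       arms = data.table::fread(file.path(dir, "arms.bed"),
                                header = FALSE,
                                col.names = c("chrom", "start", "end",
                                              "name")),
       atlas = atlas, mixture_meth = mixture,
       chrom_sizes = stats::setNames(sizes$size, sizes$chrom),
       gene_sets = gene_sets, report_paths = reports)
}

#' Build the tiled methylome directly from a simulated bundle
#'
#' Convenience path that skips the file round-trip: assembles the
#' in-memory counts into a `cpg_counts` object, applies the default
#' filters and tiles. Equivalent to reading every written report.
#'
#' @param cohort A `sim_cohort` bundle.
#' @param cfg A [filter_config()].
#' @return A `meth_tiles` object.
#' @export
cohort_tiles <- function(cohort, cfg = filter_config()) {
  x <- structure(list(sites = cohort$sites, meth = cohort$meth,
                      total = cohort$total, samples = cohort$samples),
                 class = "cpg_counts")
  tile_100bp(filter_sites(x, cfg))
}
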