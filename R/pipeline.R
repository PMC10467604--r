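#' Pipeline configuration
#'
#' Collects every input path and threshold of the end-to-end run. All
#' thresholds are surfaced with their standard defaults: DMR FDR 0.05
#' and 20 pp minimum difference, eQTM FDR 0.1 and 1 Mb cis window,
#' coverage bounds 10-500x, 1 kb promoters, 10 Mb instability length
#' cutoff.
#'
#' @param cohort_dir Directory laid out as by [write_cohort()].
#' @param out_dir Output directory.
#' @param contrasts List of `c(groupA, groupB)` subtype pairs.
#' @param covariates Covariate column names in the metadata.
#' @param fdr_dmr,min_diff_pp,fdr_eqtm,cis_bp,min_cov,max_cov,promoter_bp,inst_min_len
#'   Stage thresholds.
#' @param mira_bins,mira_flank_bp Region-set profile geometry.
#' @param seed Seed for the stages that randomise (random matched
#'   regions).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort_dir, out_dir,
                            contrasts = list(c("IMU", "KRT"),
                                             c("IMU", "HPVneg"),
                                             c("KRT", "HPVneg")),
                            covariates = c("sex", "age", "smoking",
                                           "stage"),
                            fdr_dmr = 0.05, min_diff_pp = 20,
                            fdr_eqtm = 0.1, cis_bp = 1e6,
                            min_cov = 10, max_cov = 500,
                            promoter_bp = 1000L, inst_min_len = 10e6,
                            mira_bins = 21L, mira_flank_bp = 2000L,
                            seed = 1L) {
  cfg <- as.list(environment())
  stop_if(any(c(fdr_dmr, min_diff_pp, fdr_eqtm, cis_bp) <= 0),
          "thresholds must be positive")
  class(cfg) <- "pipeline_config"
  cfg
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full analysis pipeline
#'
#' Stage order: tile -> dmr (per contrast) -> {enrichment, gene
#' direction} -> eqtm -> instability -> region sets/deconvolution/
#' pathways. Every stage writes its table under `out_dir` and logs one
#' structured line with row counts; a manifest with md5 checksums of
#' every artifact is written last. Re-running with the same seed and
#' inputs reproduces every checksum. If the expression matrix is
#' absent the eQTM and pathway stages are skipped with a notice.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest `data.frame(file, md5, n_rows)`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  co <- read_cohort(config$cohort_dir)
  out <- function(f) file.path(config$out_dir, f)
  artifacts <- character()
  nrows <- integer()
  emit <- function(df, f) {
    write_tsv0(data.table::as.data.table(df), out(f))
    artifacts <<- c(artifacts, out(f))
    nrows <<- c(nrows, nrow(df))
  }

  ## tile ------------------------------------------------------------
  reports <- lapply(co$report_paths, read_cpg_report)
  x <- cpg_matrix(reports)
  x <- filter_sites(x, filter_config(config$min_cov, config$max_cov))
  tiles <- tile_100bp(x)
  stage_log("tile", nrow(tiles$tiles), " tiles from ", nrow(x$sites),
            " CpGs; mean tile coverage ",
            round(attr(tiles, "mean_coverage"), 1), "x")
  tile_tab <- data.table::data.table(tiles$tiles,
                                     round(meth_fraction(tiles), 4))
  emit(tile_tab, "tiles_methylation.tsv")
  emit(data.table::data.table(sample = tiles$samples,
                              global_meth = round(global_methylation(tiles), 5)),
       "global_methylation.tsv")

  ## dmr per contrast -------------------------------------------------
  md <- as.data.frame(co$metadata)
  dmr_tables <- list(); summary_rows <- list()
  for (ct in config$contrasts) {
    des <- group_design(md, ct[1], ct[2], covariates = config$covariates)
    rec <- test_tiles(tiles, des, fdr_cut = config$fdr_dmr,
                      min_diff_pp = config$min_diff_pp)
    dmr_tables[[des$contrast]] <- rec
    summary_rows[[des$contrast]] <- summarize_dmrs(rec)
    stage_log("dmr", des$contrast, ": ", attr(rec, "n_tested"),
              " tested, ", sum(rec$is_dmr), " DMRs")
    emit(rec, paste0("dmr_", des$contrast, ".tsv"))
    emit(rec[rec$is_dmr, c("chrom", "start", "end", "direction")],
         paste0("dmr_", des$contrast, ".bed"))
  }
  emit(do.call(rbind, summary_rows), "dmr_summary.tsv")

  ## enrichment -------------------------------------------------------
  classes <- co$annotations
  enr_rows <- list()
  for (nm in names(dmr_tables)) {
    rec <- dmr_tables[[nm]]
    dmrs <- rec[rec$is_dmr, ]
    if (nrow(dmrs) < 5) next
    rnd <- random_matched_regions(dmrs, co$chrom_sizes,
                                  seed = config$seed)
    fe <- fisher_enrichment(annotate_regions(dmrs, classes),
                            annotate_regions(rnd, classes))
    fe$contrast <- nm
    enr_rows[[nm]] <- fe
  }
  if (length(enr_rows) > 0) {
    emit(do.call(rbind, enr_rows), "annotation_enrichment.tsv")
    stage_log("enrich", length(enr_rows), " contrast(s) enriched against ",
              length(classes), " classes")
  }

  ## gene direction ---------------------------------------------------
  calls <- list()
  for (nm in names(dmr_tables)) {
    for (reg in c("body", "promoter")) {
      cnt <- count_gene_dmrs(dmr_tables[[nm]], co$genes, reg,
                             config$promoter_bp)
      cl <- call_direction(cnt, nm)
      cl$region <- reg
      calls[[paste(nm, reg)]] <- cl
    }
  }
  gene_calls <- data.table::rbindlist(calls)
  emit(gene_calls, "gene_direction_calls.tsv")
  stage_log("genes", nrow(co$genes), " genes, ",
            sum(gene_calls$direction %in% c("hyper", "hypo")),
            " directional region calls")

  ## eqtm ---------------------------------------------------------------
  if (is.null(co$expression)) {
    stage_log("eqtm", "expression matrix absent; stage skipped")
  } else {
    keep <- filter_eqtm_tiles(tiles)
    xs <- subset_tiles(tiles, which(keep))
    des0 <- group_design(md, config$contrasts[[1]][1],
                         config$contrasts[[1]][2],
                         covariates = config$covariates)
    all_samples <- md$sample
    Xc <- stats::model.matrix(~ ., md[match(all_samples, md$sample),
                                      config$covariates,
                                      drop = FALSE])[, -1, drop = FALSE]
    rownames(Xc) <- all_samples
    pairs <- cis_pairs(xs, co$genes, config$cis_bp)
    eq <- fit_eqtm(pairs, xs, co$expression, Xc,
                   fdr_cut = config$fdr_eqtm)
    stage_log("eqtm", sum(keep), " tiles, ", nrow(pairs),
              " cis pairs, ", sum(eq$significant), " significant")
    ov <- eqtm_dmr_overlap(eq[eq$significant, ],
                           data.table::rbindlist(dmr_tables))
    emit(eq, "eqtm_pairs.tsv")
    emit(ov$summary, "eqtm_dmr_overlap.tsv")
  }

  ## instability --------------------------------------------------------
  inst <- instability_scores(co$cna_seg, co$arms,
                             min_len = config$inst_min_len)
  gm <- global_methylation(tiles)
  dc <- deconvolve_cohort(co$mixture_meth, co$atlas)
  meth_for_corr <- dc$cancer_meth_mean
  meth_for_corr[is.na(meth_for_corr)] <- gm[is.na(meth_for_corr)]
  corr <- methylation_instability_correlation(
    meth_for_corr, inst,
    stats::setNames(md$subtype, md$sample))
  stage_log("instability", nrow(inst), " samples; Pearson r = ",
            round(corr$pearson_r, 3))
  emit(inst, "instability_scores.tsv")
  emit(data.frame(pearson_r = corr$pearson_r, p = corr$p, n = corr$n),
       "instability_methylation_correlation.tsv")
  emit(corr$group_means, "instability_group_means.tsv")
  emit(data.table::data.table(sample = rownames(dc$fractions),
                              round(dc$fractions, 4),
                              cancer_meth_mean =
                                round(dc$cancer_meth_mean, 4)),
       "deconvolution.tsv")

  ## region sets + pathways --------------------------------------------
  mira_rows <- list()
  for (nm in names(co$region_sets)) {
    pr <- mira_profile(tiles, co$region_sets[[nm]],
                       n_bins = config$mira_bins,
                       flank_bp = config$mira_flank_bp)
    sc <- mira_score(pr)
    sc$region_set <- nm
    mira_rows[[nm]] <- sc
  }
  if (length(mira_rows) > 0) {
    emit(do.call(rbind, mira_rows), "mira_scores.tsv")
    stage_log("regsets", length(mira_rows), " region sets profiled")
  }
  if (!is.null(co$expression) && length(co$gene_sets) > 0) {
    ps <- do.call(rbind, lapply(names(co$gene_sets), function(nm)
      pathway_score(co$expression, co$gene_sets[[nm]], nm)))
    emit(ps, "pathway_scores.tsv")
  }

  manifest <- data.frame(file = basename(artifacts),
                         md5 = unname(tools::md5sum(artifacts)),
                         n_rows = nrows)
  write_tsv0(manifest, out("manifest.tsv"))
  stage_log("done", length(artifacts), " artifacts in ", config$out_dir)
  invisible(manifest)
}
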