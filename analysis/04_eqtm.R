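#!/usr/bin/env Rscript
# cis-eQTM scan: filter tiles (coverage, CV, fully-unmethylated count),
# pair them with genes within 1 Mb of the TSS, fit covariate-adjusted
# linear models, and cross-tabulate significant eQTMs against DMRs.

library(methylotype)

co <- read_cohort("scratch/cohort")
tiles <- readRDS("scratch/tiles.rds")
md <- as.data.frame(co$metadata)
covs <- c("sex", "age", "smoking", "stage")
X <- stats::model.matrix(~ ., md[covs])[, -1, drop = FALSE]
rownames(X) <- md$sample

keep <- filter_eqtm_tiles(tiles)
xs <- subset_tiles(tiles, which(keep))
pairs <- cis_pairs(xs, co$genes, max_dist = 1e6)
eq <- fit_eqtm(pairs, xs, co$expression, X, fdr_cut = 0.1)
cat(sum(keep), "tiles pass the eQTM filters;", nrow(pairs),
    "cis pairs tested;", sum(eq$significant), "significant (FDR<0.1)\n")

dmr_all <- data.table::rbindlist(lapply(
  list.files("scratch", pattern = "^dmr_.*rds$", full.names = TRUE),
  readRDS))
ov <- eqtm_dmr_overlap(eq[eq$significant, ], dmr_all)
write.table(ov$summary, "results/eqtm_dmr_overlap.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("eQTM tiles overlapping a DMR: %d of %d (%d%%); %d%% negative overall\n",
            ov$summary$n_overlap, ov$summary$n_unique_tiles,
            ov$summary$overlap_pct, ov$summary$negative_pct_all))

# recovery of the planted methylation-coupled genes
gt <- jsonlite::read_json("scratch/cohort/ground_truth.json",
                          simplifyVector = TRUE)
planted <- gt$planted_eqtms
if (length(planted) > 0) {
  sig_genes <- unique(eq$gene[eq$significant])
  rec_rate <- mean(planted$gene %in% sig_genes)
  cat(sprintf("Planted eQTM genes recovered: %.0f%% (%d of %d)\n",
              100 * rec_rate, sum(planted$gene %in% sig_genes),
              nrow(planted)))
}
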