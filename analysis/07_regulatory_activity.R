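#!/usr/bin/env Rscript
# Region-set regulatory activity (MIRA-style dip scores), expression
# pathway scores, and their correlation: the keratinization link.

library(methylotype)

co <- read_cohort("scratch/cohort")
tiles <- readRDS("scratch/tiles.rds")
subtype <- co$metadata$subtype[match(tiles$samples, co$metadata$sample)]

score_rows <- list()
for (nm in names(co$region_sets)) {
  pr <- mira_profile(tiles, as.data.frame(co$region_sets[[nm]]),
                     n_bins = 21L, flank_bp = 2000L)
  sc <- mira_score(pr)
  sc$region_set <- nm
  score_rows[[nm]] <- sc
  cat(sprintf("%-10s mean score by subtype: %s\n", nm,
              paste(names(tapply(sc$score, subtype, mean)),
                    round(tapply(sc$score, subtype, mean), 2),
                    collapse = "  ")))
}
mira <- do.call(rbind, score_rows)
write.table(mira, "results/mira_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

ps <- do.call(rbind, lapply(names(co$gene_sets), function(nm)
  pathway_score(co$expression, co$gene_sets[[nm]], nm)))
write.table(ps, "results/pathway_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# dip scores of the TF binding-site set track keratinization
tf <- mira[mira$region_set == "TFBS_A", ]
ker <- ps[ps$set == "keratinization", ]
r <- cor.test(tf$score[match(ker$sample, tf$sample)], ker$score)
cat(sprintf("TFBS activity vs keratinization score: Pearson r = %.2f (p = %.2g)\n",
            unname(r$estimate), r$p.value))
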