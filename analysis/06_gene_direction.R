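#!/usr/bin/env Rscript
# Gene-centric DMR summaries: promoter/body counts, direction calls,
# and the cross-cohort direction cross-tab on a perturbed copy of the
# calls (stand-in for an external cohort's direction table).

library(methylotype)

co <- read_cohort("scratch/cohort")
rec_ik <- readRDS("scratch/dmr_IMU_vs_KRT.rds")
rec_ih <- readRDS("scratch/dmr_IMU_vs_HPVneg.rds")
rec_kh <- readRDS("scratch/dmr_KRT_vs_HPVneg.rds")

rows <- list()
for (nm in c("IMU_vs_KRT", "IMU_vs_HPVneg", "KRT_vs_HPVneg")) {
  rec <- get(paste0("rec_", c(IMU_vs_KRT = "ik", IMU_vs_HPVneg = "ih",
                              KRT_vs_HPVneg = "kh")[[nm]]))
  for (reg in c("promoter", "body")) {
    cl <- call_direction(count_gene_dmrs(rec, co$genes, reg), nm)
    cl$region <- reg
    rows[[paste(nm, reg)]] <- cl
  }
}
calls <- data.table::rbindlist(rows)
write.table(calls, "results/gene_direction_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
tab <- table(calls$contrast, calls$direction)
cat("Direction calls by contrast:\n"); print(tab)

# literature-style concordance: treat the IMU-vs-HPV(-) body calls of
# the hypermethylated genes as the 'reported' table and ask which
# subtype carries the signal
body_imu <- calls[calls$contrast == "IMU_vs_HPVneg" &
                    calls$region == "body", ]
body_krt <- calls[calls$contrast == "KRT_vs_HPVneg" &
                    calls$region == "body", ]
lit <- data.frame(gene = body_imu$gene[body_imu$direction %in%
                                         c("hyper", "hypo")],
                  direction = body_imu$direction[body_imu$direction %in%
                                                   c("hyper", "hypo")])
lc <- literature_concordance(body_imu, body_krt, lit)
write.table(lc$summary, "results/literature_concordance.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(lc$summary)

# cross-cohort direction stability: site-level calls against a copy
# with 10% of directions flipped (emulating a discordant second cohort)
sites <- rec_ik[rec_ik$is_dmr, c("chrom", "start", "end", "direction")]
set.seed(11)
other <- sites
flip <- sample(nrow(other), round(0.1 * nrow(other)))
other$direction[flip] <- ifelse(other$direction[flip] == "hyper",
                                "hypo", "hyper")
ct <- direction_crosstab(sites, other)
cat(sprintf("Cross-cohort reversed fraction: %.3f (%d of %d shared sites)\n",
            ct$reversed_frac, nrow(ct$reversed), ct$n_shared))
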