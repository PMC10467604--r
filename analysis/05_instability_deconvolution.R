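#!/usr/bin/env Rscript
# CNA-based genomic instability scores, reference-based deconvolution
# for cancer cell-specific methylation, and their correlation.

library(methylotype)

co <- read_cohort("scratch/cohort")
tiles <- readRDS("scratch/tiles.rds")
md <- as.data.frame(co$metadata)

inst <- instability_scores(co$cna_seg, co$arms)
write.table(inst, "results/instability_scores.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

dc <- deconvolve_cohort(co$mixture_meth, co$atlas)
fr <- data.frame(sample = rownames(dc$fractions),
                 round(dc$fractions, 4),
                 cancer_meth = round(dc$cancer_meth_mean, 4))
write.table(fr, "results/deconvolution.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

meth_cs <- dc$cancer_meth_mean
gm <- global_methylation(tiles)
meth_cs[is.na(meth_cs)] <- gm[is.na(meth_cs)]
labels <- stats::setNames(md$subtype, md$sample)
corr <- methylation_instability_correlation(meth_cs, inst, labels)
cat(sprintf("Cancer-specific methylation vs instability: Pearson r = %.2f (p = %.2g, n = %d)\n",
            corr$pearson_r, corr$p, corr$n))
print(corr$group_means, row.names = FALSE)
write.table(corr$group_means, "results/instability_group_means.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
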