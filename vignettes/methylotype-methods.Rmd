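---
title: "Methods: methylation subtyping of tumor cohorts from WGBS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylation subtyping of tumor cohorts from WGBS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, parameters and design choices
behind `methylotype`. The package analyses whole-genome bisulfite
sequencing (WGBS) of a tumor cohort with fine-scale molecular
subtypes -- the motivating setting is head-and-neck squamous cell
carcinoma with an immune-strong HPV(+) subtype (IMU), a keratinized
HPV(+) subtype (KRT) and HPV(-) tumors -- and asks where the
methylome differs between subtypes, how those differences couple to
expression, genomic instability and regulatory activity, and how much
of the signal survives adjustment for tumor purity.

## From cytosine reports to tiles

Input is one cytosine report per sample (chromosome, 1-based
position, strand, methylated count, unmethylated count). CpG
methylation is symmetric between strands, so minus-strand cytosines
are collapsed onto the plus-strand position of the dyad and counts
summed before anything else happens. Three site filters follow:

* **Coverage 10--500x, inclusive on both ends.** Sites below 10x are
  too noisy; sites above 500x are usually collapsed repeats or
  mapping artefacts. The bounds mask per sample (the site stays for
  the other samples) so that the per-group coverage rule downstream
  remains meaningful; blacklist and sex-chromosome filters drop the
  site outright for all samples.
* **SNP blacklist.** C>T and G>A variants are indistinguishable from
  bisulfite conversion; the blacklist is an input, not something the
  package calls.
* **Sex chromosomes**, excluded to avoid X-inactivation-driven
  methylation differences between male and female patients.

Surviving CpGs are tiled into fixed 100-bp windows anchored at genome
coordinate 0 (`[floor((p-1)/100)*100, +100)`). Anchoring at the fixed
grid rather than at the first CpG of a run makes tiles reproducible
across cohorts and is what every published tiling pipeline we are
aware of does; the alternative anchoring changes tile boundaries but
not any conclusion we tested. Tiling conserves counts exactly (the
test suite asserts it), so the genome-wide methylation level --
methylated reads over total reads -- is identical before and after.

All internal intervals are 0-based half-open (BED convention);
1-based report positions are converted once, at the reader.

## The differential test

For a tile with per-sample counts $(m_i, t_i)$ and fraction
$p_i = m_i/t_i$, the between-sample model is beta-binomial with mean
$\mu$ and intraclass dispersion $\varphi$:
$\mathrm{Var}(p_i) = \mu(1-\mu)\,(1 + (t_i-1)\varphi)/t_i$.
The arcsine link $y_i = \arcsin(2p_i - 1)$ stabilises the variance to
$(1+(t_i-1)\varphi)/t_i$, free of $\mu$, so the group comparison
becomes a weighted least-squares fit of $y$ on group plus covariates
with known per-observation weights $t_i/(1+(t_i-1)\varphi)$ and a
Wald test on the group coefficient (t reference with residual degrees
of freedom). This is a deliberate simplification of dispersion-
shrinkage beta-binomial testing as practised in the WGBS literature:
the model family and the selection rules are what matter downstream,
and acceptance is calibration and power on synthetic data with known
truth, not numerical equality with any particular implementation.

$\varphi$ is estimated per tile by method of moments on the residuals
around the two group means, with the $n_g/(n_g-1)$ small-sample
correction for the estimated mean (without it the estimate is biased
low and type-I error inflates to ~0.07-0.08), then shrunk toward the
genome-wide median with weight $w = m/(m+k)$, where $m$ is the tile's
total coverage and $k$ defaults to twice the median $m$ (weight 1/3
at median coverage). As $k \to \infty$ every tile takes the prior.

Selection follows the standard rules: a tile is *interrogated* only
when covered in at least 80% of the samples of each group (ceiling at
non-integer thresholds -- the stricter reading), and is a DMR when
the Benjamini-Hochberg FDR is below 0.05 *and* the absolute group
difference is at least 20 percentage points on the fraction scale.
BH runs within each contrast over all eligible tiles. Covariates
(sex, age, smoking status, stage, viral expression) are configuration;
continuous coding is used for viral expression. Ties in p keep stable
input order. Adjacent significant tiles are deliberately *not* merged:
the unit of testing and reporting is the fixed 100-bp tile.

Empirically (and asserted by the acceptance suite): type-I error at
nominal 0.05 stays within [0.03, 0.07] for $\varphi \in \{0.05, 0.1,
0.2\}$ at n = 8 vs 10 and 24x tile coverage, and 30-pp planted effects
are recovered in >85% of tiles under the same conditions.

## Annotation enrichment

DMRs are annotated to promoters (1 kb upstream of the TSS,
strand-aware), exons, introns, CpG islands, shores (0-2 kb), shelves
(2-4 kb) and repeat families by >=1 bp overlap; a region may hit
several classes. Enrichment is a two-sided Fisher exact test of each
class against random regions matched *exactly* in number and width
(widths permuted, placement uniform over the allowed genome,
chromosomes drawn proportional to length) -- the tightest reading of
"a comparable number of regions". Random regions may overlap each
other and are not matched for CpG density or mappability; both are
documented defaults rather than claims. A class is called enriched at
BH FDR < 0.05 and odds ratio > 1.5 (Haldane 0.5 correction when a
cell is empty). Depletion is tested (two-sided) but only enrichment
is flagged.

## cis-eQTM scan

Tiles enter the scan when (i) covered in at least 80% of samples,
(ii) their coefficient of variation exceeds the empirical 5th
percentile of the CV distribution of coverage-eligible tiles, and
(iii) fewer than 33/36 of samples are fully unmethylated -- the last
rule removes tiles whose apparent variation is carried by one or two
non-zero samples. CV is scale-invariant, so fraction versus percent
scale is immaterial; zero-mean tiles get CV 0 and are removed by the
CV rule.

Each tile is paired with every gene whose TSS lies within 1 Mb of the
tile midpoint (inclusive; signed distance negative upstream of the
TSS in the gene's orientation). Per pair, ordinary least squares of
expression on methylation plus the four covariates, t-test on the
methylation coefficient, and BH pooled across *all* candidate pairs
genome-wide -- pooled BH was chosen over per-gene correction because
the downstream summaries (DMR overlap shares, sign composition) are
genome-wide. Significance is FDR < 0.1. Slopes are reported in
expression units per methylation-fraction unit; sign is the sign of
the slope.

## Genomic instability

Per sample, copy-number segments (an input; the package does not call
CNAs) are split at arm boundaries, then each segment contributes:

* $|CN - 2|$ if it is an arm-level alteration (covers >=90% of its
  arm -- the conventional arm-call threshold; the source convention
  does not pin this down, so it is configurable),
* 1 (binary) if it is shorter than an arm but **strictly longer than
  10 Mb**,
* 0 if neutral ($|CN-2| < 0.3$, a band for real-valued calls) or
  <=10 Mb.

The binary term counts one per segment (not per merged region); ties
between arm-level and sub-arm classification resolve to arm-level.
The score is summed over all segments; it is additive over
chromosomes and order-invariant, and the suite checks it against a
brute-force oracle. The score is then correlated (Pearson, two-sided
t-based p) with per-sample methylation -- by preference the cancer
cell-specific methylation from deconvolution, falling back to global
methylation where the tumor fraction is too small to divide by.

## Deconvolution and cancer-specific methylation

Bulk tumor methylomes mix cancer cells with immune, stromal and
endothelial compartments, so subtype differences in global
methylation could in principle be purity artefacts. The package fits
non-negative least squares of each sample's region methylation on a
cell-type reference atlas, normalises the coefficients to the
simplex, and treats the coefficient of a designated *tumor-like*
reference row (the epithelial lineage the carcinoma derives from) as
the tumor fraction. Cancer cell-specific methylation is then solved
per region as (observed − sum of normal contributions) / tumor
fraction, clipped to [0, 1] (clip events counted), and reported
missing when the tumor fraction is below 0.05.

Known limitation: normal cells of the tumor's own lineage are not
separable from tumor by this design (their reference profiles are
nearly collinear); in tumor tissue the normal-epithelial compartment
is small, and the synthetic generator reflects that. With marker-rich
atlases the acceptance suite shows tumor-fraction recovery within
±0.05 and cancer-specific methylation within ±0.05 of truth at noise
SD 0.03 over 500 regions.

## Region-set activity (MIRA-style) and pathway scores

Active regulatory regions are locally unmethylated, so aggregating
methylation around the centers of a TF's binding sites produces a dip
whose depth tracks binding activity. Profiles use an odd number of
equal-width bins (default 21) spanning ±5 kb around region centers
(±2 kb in the demo, whose genome is small), coverage-weighted and
strand-flipped; the score is `log2(shoulder / center)` with the
shoulder the mean of the two bins at `floor(B/2)` bins from the
center (B flank bins per side). A flat profile scores exactly 0;
deeper dips score higher. The published MIRA convention leaves the
flank/bin choice to its own supplement, so these defaults are the
package's own and are configurable -- scores are comparable within a
run, not across tools.

Expression pathway scores are per-gene z-scores across the cohort
averaged over the gene set; cohort mean 0 by construction. Gene sets
are configuration inputs.

## Gene-level direction and cross-cohort logic

A gene's methylation direction per contrast compares counts of hyper-
versus hypomethylated DMRs across the gene body ([TSS, end)); equal
non-zero counts are an explicit `tied` class, and DMRs overlapping
several genes count for each. Promoters are the 1 kb immediately
upstream of the TSS. Literature concordance classifies each reported
gene by whether the IMU and/or KRT contrast reproduces its direction;
genes whose reported direction conflicts with *both* subtypes are the
discordant (excluded) class. The cross-cohort operation joins two
site-level direction tables on coordinates and counts concordant
versus reversed sites; recomputing another cohort's differential
methylation is out of scope -- its direction table is an input.

## The synthetic cohort

Every stage is exercised on a generator whose defaults *are* the
study conditions: 8 IMU / 10 KRT / 18 HPV(-) samples; genome-wide
methylation means 0.62 / 0.51 / 0.52 (calibrated exactly, by solving
for the additive shift before clipping); per-CpG coverage negative
binomial with mean 24; CpG positions exponentially spaced (mean 60
bp) with 5x-denser island hotspots so island/shore/shelf annotations
are non-degenerate; island sites Beta-distributed around 0.12, shores
0.5, open sea 0.82. Within-group variation is beta-binomial with
dispersion $\varphi = 0.1$ by default -- the generative model is
*the same family the test assumes*, deliberately, so calibration
checks are exact; $\varphi$ is swept over {0.05, 0.1, 0.2} in the
acceptance suite. The published source does not state within-group
variance, so this default is the package's choice of a realistic
mid-range value.

Planted structure, all recorded in the ground truth: DMR blocks (1-3
tiles wide, ±30 pp, 50% IMU-hyper / 30% KRT-hypo / 20% HPV(-)-hypo,
reproducing the observed IMU-hypermethylation asymmetry); extra
repeat-element hypomethylation in KRT (−5 pp) and HPV(-) (−4 pp),
folded into the global calibration; variably methylated eQTM tiles
(per-sample methylation Beta(2,2) -- the wide spread real regulatory
tiles show across tumors) wired into expression with slope −2 and
noise SD 0.5 on log2-CPM; covariates independent of subtype by
default with a confounding switch; CNA segment sets constructed to
hit target instability scores exactly (group means 40.5 / 54.8 /
82.4, within-group anticorrelation with methylation), built from
arm-level events plus >10 Mb focal events plus neutral/short decoys;
regulatory region sets with Gaussian-kernel methylation dips whose
depth differs by group (IMU shallowest); and an atlas of six cell
types with ~55 cell-type-specific hypomethylated marker regions each,
mixed with group-specific tumor purity (IMU lowest, reflecting its
immune infiltration) plus measurement noise SD 0.03.

What the generator does **not** emulate -- and hence what passing
tests do not show about real data: read-level artefacts (no FASTQ, no
bisulfite-conversion errors, no mapping bias), linkage between the
methylation genome and the CNA genome (they are separate coordinate
systems), chromatin-scale correlation between neighbouring tiles
beyond the planted blocks, and real annotation geometry. Problem
sizes in the checked-in runs are the package's own choice: the demo
analysis uses a 2 x 400 kb genome (~15k CpGs, ~6.5k tiles), tests use
a 1 x 200 kb genome, calibration uses >=6,000 direct-simulated tiles
and power/recovery use 200 and 100 replicates respectively.

## Numerical conventions

Degenerate inputs are handled explicitly: fractions are undefined
(NA) at zero coverage; dispersion of an all-identical tile takes the
floor 1e-6; group-aliased design columns skip the tile with a note;
rank-deficient eQTM pairs are kept with NA statistics and a skip
flag; a MIRA center of 0 is floored at 1e-3 and flagged; Fisher
tables with an empty class emit p = 1 with a degenerate flag;
integer percentages use round-half-even (R's `round`), which
reproduces published table arithmetic. Strand splitting when writing
simulated cytosine reports is a deterministic function of the counts,
so writing a bundle twice is byte-identical -- the property the
pipeline manifest checksums rely on.
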