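# survscan

Selection scans on survivor populations **within a single generation**.

When a sown plant population is exposed to field conditions for a few
years, only a fraction of individuals survive. Because there is no
reproduction, recombination or migration in between, any systematic shift
in allele frequency between the original seed lot and the survivors is the
direct footprint of viability selection. `survscan` implements the
statistics of such scans for outbreeding crops genotyped by sequencing
(GBS) — individuals or pooled samples — together with a forward simulator
of the whole experiment for calibration and power analysis. The motivating
setting is perennial forage legumes (e.g. red clover) where survivor
populations from replicate field plots are compared with the original
cultivar, but nothing in the package is species-specific.

## The statistic

For one SNP and two populations with tracked-allele frequencies *q₁*, *q₂*:

- **F_ST** (two-population variance form):
  `F_ST = (q₁ − q₂)² / (4 q̄ (1 − q̄))`, with `q̄ = (q₁ + q₂)/2`.
- **Significance**: `X² = 2N · F_ST`, where `2N` is the sum of genotyped
  gametes in the two populations, referred to the χ² distribution with
  1 df.
- **Replicate intersection**: a locus is called selected at level *P* only
  if the test is significant in **all** *n* replicate comparisons
  (survivor plot vs original, or plot vs opposite-treatment group mean).
- **Combined FDR**: `FDR = l · Pⁿ / d`, the number of loci expected to
  pass the intersection by chance (*l* loci tested, each passing *n*
  independent tests with probability *Pⁿ*) over the number *d* observed to
  pass.
- Hits are confirmed with a two-sided **Fisher exact test** on pooled
  survivor vs original gamete counts, and treatment effects on allele
  frequencies are partitioned with a balanced **two-way ANOVA**
  (stand type × seeding density).

The package also estimates allele frequencies from pooled sequencing
(ratio of summed reads across replicate libraries), quantifies
pool-vs-individual accuracy by read-depth bin, and provides PCA views of
population differentiation and individual-level structure with a
minor-subpopulation proportion summary.

## Worked example

Simulate a study (4 replicate survivor plots of 48 sampled individuals vs
an original sample of 88, with 3 loci under moderate viability selection
among 2000), then run the full scan:

```r
library(survscan)

cfg <- sim_config(seed = 7, L = 2000, n_selected = 3,
                  survival_probs = matrix(rep(c(0.1, 0.35, 1), each = 3),
                                          ncol = 3))
sim <- simulate_experiment(cfg, gbs_reads = TRUE)
out <- run_study1(sim$study1$genotypes, sim$study1$pops, verbose = TRUE)
#> l = 1925 SNPs tested in all 4 comparisons
#> P < 0.1   : d = 2, FDR = 0.0963
#> P < 0.05  : d = 2, FDR = 0.00602
#> P < 0.01  : d = 1, FDR = 1.93e-05

round(out$report[, c("q_ref", "mean_q", "abs_delta_q", "mean_fst",
                     "fisher_p")], 4)
#>    q_ref mean_q abs_delta_q mean_fst fisher_p
#> 1 0.1267 0.2796      0.1529   0.0364   0.0002
#> 2 0.4345 0.2982      0.1363   0.0201   0.0029
```

`l` is the number of loci testable in all four comparisons after the GBS
filters (≥10 reads per call, 2 per allele for heterozygotes, ≥25 genotyped
individuals per population, MAF > 0.05 in the original). Both reported
hits are planted loci: their original-population frequency (`q_ref`, the
minor allele), mean survivor frequency, absolute shift, mean F_ST across
the four plots, and the confirming Fisher p-value are the columns a
selection-scan results table reports.

The arithmetic building blocks are exposed directly:

```r
combined_fdr(4966, 0.1, 4, 27)$fdr   # 0.0184
pairwise_fst(0.46, 0.68)             # 0.0494
```

## The analysis workflow

Numbered drivers under `analysis/` run the three studies end to end on a
simulated experiment and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R              # synthetic field experiment
Rscript analysis/02_study1_scan.R           # survivors vs original scan
Rscript analysis/03_study2_pool_accuracy.R  # pooled vs individual freqs
Rscript analysis/04_study3_treatment_scan.R # treatment contrasts + ANOVA
```

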