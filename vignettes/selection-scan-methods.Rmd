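---
title: "Detecting within-generation viability selection with replicate survivor populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting within-generation viability selection with replicate survivor populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(survscan)
```

## The problem

A synthetic outbred cultivar is sown in replicate field plots. After two
to three growing seasons most plants are dead; the survivors in each plot
are a selected subset of the same generation that was sown — no
reproduction, recombination or migration has happened in between. Any
allele whose frequency has shifted consistently in *every* replicate plot,
relative to the original seed lot, is a candidate for viability selection:
within one generation, drift cannot produce consistent shifts, only
survival can.

`survscan` implements this scan for GBS-genotyped material: quality
filters, allele-frequency estimation from individuals and from pooled
samples, the per-SNP F_ST/χ² test with a replicate-intersection rule and a
combined false-discovery-rate estimate, Fisher exact confirmation,
principal-component summaries of structure, and a balanced two-way ANOVA
for treatment contrasts. A forward simulator generates every input the
pipeline consumes, with ground truth, so the operating characteristics of
the scan can be measured.

## Model and procedure

### Filters

Individual GBS calls are kept when they have at least
`min_total_reads = 10` reads in total and, for heterozygotes, at least
`min_reads_per_het_allele = 2` reads of *each* allele; failing calls are
set missing rather than demoted, because a heterozygote with one unseen
allele is indistinguishable from allelic dropout. A SNP enters the scan
when it is genotyped in at least `min_genotyped_per_pop = 25` individuals
in *every* population and its minor allele frequency exceeds
`maf_threshold = 0.05` (strict inequality) in the reference population.
MAF is computed by gamete counting over retained calls — the same counts
that define `2N` — not from dosage means. Pooled samples are filtered by
an inclusive read-depth window per replicate library (10–126 reads for
replicate DNA-pool libraries; 100–499 with the MAF rule in every sample
for leaf pools), read as inclusive because depth is integral.

### Frequencies

From individuals, `q = (alt gametes) / 2N` with `2N` twice the genotyped
individuals. From pools, replicate libraries are merged by *summing*
reads before the ratio — the ratio of sums weights each library by its
information content, whereas a mean of per-library ratios would let a
10-read library count as much as a 100-read one. Replicate pools of a plot
are averaged unweighted (they are biological re-samplings of one plot, not
sequencing replicates). The tracked allele is fixed per SNP as the minor
allele of the reference population (the original population, or the first
plot in treatment scans) and kept identical across populations:
per-population re-polarization would corrupt cross-population differences.
Pool gamete counts are nominal (`2 × 100` for 100-plant pools) and
configurable, since the effective number of gametes sampled through a pool
is smaller than the census count.

### The test

For each SNP and comparison, `F_ST = (q₁−q₂)²/(4 q̄ (1−q̄))` with
`q̄ = (q₁+q₂)/2` — the two-population variance form — and
`X² = 2N·F_ST ~ χ²(1)` with `2N` the summed gamete count of the pair.
One degree of freedom is used because a biallelic SNP gives a 2×2
allele-count table. No continuity correction is applied. A SNP is
*selected at level P* only when all required comparisons are individually
significant; the direction of the shift is recorded (and reported) but not
required, matching the significance-only intersection rule. In the
treatment mode each of the 8 plots is compared against the unweighted mean
frequency of the opposite stand-type group, which carries the *sum* of its
four pools' gamete counts; the combined FDR still uses `n = 4` because
only four of the eight F_ST values are independent.

The combined FDR is `l·Pⁿ/d`: with `l` loci tested (only loci testable in
*all* comparisons count) each passes `n` independent level-`P` tests with
probability `Pⁿ` under the null, so `l·Pⁿ` false loci are expected among
the `d` observed. Hits are confirmed with a two-sided Fisher exact test
(hypergeometric enumeration; p is the sum of table probabilities not
exceeding the observed one) comparing the combined survivors' gamete
counts with the original's.

### Treatment ANOVA

Per-plot frequencies of candidate SNPs are decomposed by a balanced
fixed-effects two-way ANOVA (stand type, seeding density, interaction; one
df each; error df = plots − 4). In the balanced case type-I and type-III
sums of squares coincide and `SS` is additive to 1e-10, which the tests
assert against an explicit cell-mean oracle. All-equal responses return
p = 1 by convention. No multiple-testing correction is applied across
candidate SNPs at this stage — the stage consumes a list already selected
by an outlier method, and classification at per-SNP P < 0.05 is the
reported convention. Star levels are *, **, *** for 0.05, 0.01, 0.001.
The "difference between stand types" column is the absolute difference of
factor-level mean frequencies; no formula is standard here, so the obvious
one is used and documented.

### PCA and structure

Population-level PCA takes the populations × SNPs frequency matrix,
centers each SNP (no unit-variance scaling — scaling would up-weight
low-MAF SNPs; a flag exposes it), and decomposes by singular values.
Individual-level PCA uses dosages with per-SNP mean imputation of missing
calls — the standard genotype-PCA choice that adds no between-individual
structure. The minor-subpopulation proportion is computed by an exact
one-dimensional 2-means on PC1: the optimum of 1-D 2-means is always a
split point of the sorted scores, so it is found by scanning the n−1
splits — deterministic, with no random restarts, and invariant to the sign
of PC1. How a "minor cluster" is delimited is not standardized; this rule
is the package's choice.

## The simulator

`sim_config()` defines the study conditions. Defaults, and why:

| parameter | default | rationale |
|---|---|---|
| `L` | 2000 | enough loci for rate estimates at desk scale |
| `base_freq_range` | [0.05, 0.95] | MAF filter makes rarer alleles unobservable |
| `minor_fraction`, `fst0` | 0.17, 0.02 | weak two-subpopulation structure: PC1/PC2 of genotypes explain only a few percent |
| `N_sown`, `N_survivors` | 2000, 500 | ~25% survival, the range reported for dense pure stands after 2–3 seasons |
| `sample_n_original`, `sample_n_survivor` | 88, 48 | field sample sizes (2N = 176 vs 96) |
| `depth_mean`, `depth_dispersion` | 30, 5 | GBS per-call depth, overdispersed |
| `seq_error` | 0.005 | per-read error |
| `pool_n`, `pool_depth_mean` | 100, 250 | leaf pools of 100 plants in the 100–499 window |
| `dna_pool_depth_mean` | 40 | per replicate library; 7 merged libraries land in the 10–600+ range |
| `leaf_concentration` | 1 | Dirichlet tissue contribution; calibrated so replicate leaf-pool deviation is ≈0.05 vs ≈0.035 for DNA pools |
| `high_depth_cutoff`, `high_depth_beta` | 600, Beta(1,4) | phenomenological paralog-collapse contamination above 600 reads |

Base frequencies are uniform; the two subpopulations are Balding–Nichols
draws with drift parameter `2·fst0`, which makes the realized pairwise
F_ST between the subpopulation frequency vectors ≈ `fst0` (the tests
verify the calibration). Genotypes are Hardy–Weinberg within
subpopulation.

**Viability selection.** Each individual's weight is the product over
selected loci of its genotype survival probability (p₀, p₁, p₂), i.e.
multiplicative fitness with no epistasis. Survival is an independent
Bernoulli with `pᵢ = min(1, c·wᵢ)` where `c` is solved (water-filling over
the capped individuals) so that the *expected* survivor count is exactly
`N_survivors`. For a single locus the expected post-selection frequency is
the closed form
`q' = (q²p₂ + q(1−q)p₁) / (q²p₂ + 2q(1−q)p₁ + (1−q)²p₀)`,
and the simulation matches it to within 3 standard errors over 1000 plots.

An important saturation effect follows from the model (and from first
principles): total selection intensity is bounded by the survival
fraction — at 25% survival the top-quartile truncation limit is i ≈ 1.27 —
and is *shared* across selected loci, so with `k` strong loci the realized
per-locus shift scales like 1/√k. Twenty independent loci can never
realize shifts of 0.2 each within one generation at 25% survival,
whichever per-genotype survival probabilities are planted; three can.
Calibration experiments therefore plant few strong loci when the design
requires realized shifts ≥ 0.2, and the closed-form expectation is the
reference for "expected shift". This also means that a real scan reporting
many independent loci with large one-generation shifts should be read with
the false-discovery caveat of the next section in mind.

**Sequencing.** GBS and pool depth use a per-SNP tag-abundance factor
(Gamma with shape = rate = dispersion) with Poisson counts around
`mean × factor`: marginally negative-binomial, but *correlated across
libraries*, because restriction-site quality is a property of the locus.
Without this correlation, joint depth-window filters across 7–12 libraries
would retain almost nothing, which contradicts observed retention rates.
Pooled read fractions are contribution-weighted means of `dosage/2`
(equal weights for DNA pools; Dirichlet weights for leaf pools). Above the
high-depth cutoff a Beta-distributed contamination fraction pulls the read
fraction toward 0.5, reproducing the accuracy loss seen at extreme depths
(collapsed paralogous tags); the term is phenomenological, drawn once per
locus. Genotypes are re-called naively from reads (both alleles seen →
heterozygote) so the pipeline's filters generate realistic missingness.

What the simulator does **not** emulate: linkage between loci, epistasis,
spatially structured mortality within plots, batch effects between the
two SNP-calling rounds, and reference-bias in read mapping. Passing tests
on this generator show the statistics behave as designed under their own
assumptions — not that real field data meet those assumptions.

## Operating characteristics, including a caveat the tests document

Under neutral simulation at the field sample sizes, the per-comparison
test at P = 0.05 rejects at ≈0.06 — slightly anti-conservative because
`2N·F_ST` with the *unweighted* q̄ overstates the statistic when sample
sizes differ (it coincides with the Pearson χ² only for equal sizes) —
and the four-fold intersection keeps genome-wide hits to a handful among
thousands of loci. The acceptance tests assert both.

The combined FDR `l·Pⁿ/d`, however, assumes the `n` comparisons are
independent. They are not: every comparison shares the single original
sample, which contributes ≈35% of each test's noise at 2N = 176 vs 96.
Direct Monte Carlo of the statistic shows the null intersection rate is
≈27× the independent `P⁴` at P = 0.1, ≈106× at P = 0.05, and more extreme
further out: an original sample that happens to deviate at a locus makes
all four comparisons significant together. The realized false-discovery
proportion among intersection hits is therefore structurally larger than
`l·Pⁿ/d` suggests, and the corresponding acceptance test — which plants
20 selected loci among 2000 and compares the realized false-hit count
with the binomial band implied by the estimate — fails by design and is
left failing: it documents a genuine property of the method, not a defect
of the implementation. Enlarging the reference sample does not rescue the
estimate, because the unweighted-q̄ statistic becomes badly anti-
conservative for very unequal sample sizes. Users should treat `l·Pⁿ/d`
as an optimistic lower bound and lean on direction consistency, effect
ranking and the Fisher confirmation (which shares the same reference
sample, and hence the same caveat, but adds exactness at small counts).

Power behaves as expected otherwise: planted loci with closed-form
expected shifts ≥ 0.2 at survivor gamete counts of 96 are detected in all
four replicates at P < 0.05 in well over half the cases, and detection is
monotone in the shift and in 2N.

## Numerical choices and degenerate inputs

- F_ST returns `NA` for monomorphic pairs (q̄ ∈ {0, 1}); such loci are
  untested and excluded from `l`.
- `selected_at` is monotone across nested levels by construction; the
  levels are sorted loosest-first.
- Fisher exact uses the base-R hypergeometric implementation; the test
  suite pins it to an independent full-enumeration oracle at 1e-10.
- ANOVA p-values are 1 when the full decomposition is numerically zero
  (all responses equal); a zero error SS with non-zero effect SS gives
  p = 0.
- Zero merged pool depth gives `q = NA`; all-NA replicate groups average
  to `NA`; plots with any NA in a compared population make the SNP
  untested rather than silently dropped from single comparisons.
- Scan TSVs serialize at 17 significant digits and round-trip within
  1e-12; untested p-values serialize as `NA`.
- All randomness flows from the single `seed` in `sim_config`; replicate
  draws inside one experiment consume one stream, so identical configs
  are byte-identical. Tests that draw additional randomness after running
  the simulator use seeds distinct from the simulator's to avoid
  replaying its stream.

## Problem sizes used by the test and acceptance suites

Calibration and power experiments use L = 2000 loci, 2000 sown and 500
surviving plants per plot, four plots, and the field sample sizes (88/48);
the closed-form check uses 1000 replicate plots; the pool-accuracy checks
use 2000–5000 loci. These sizes give Monte-Carlo error comfortably inside
the asserted bands while the full suite runs in well under a minute.

## Limitations

- The scan tests marginal per-SNP shifts; linked loci produce correlated
  hits that the FDR arithmetic treats as independent discoveries.
- Nominal pool gamete counts overstate the information in pooled
  frequencies; the χ² test on pools is anti-conservative in proportion.
- The combined FDR's independence assumption is violated by shared
  reference samples (see above); reported FDR values are optimistic.
- The 1-D 2-means subpopulation split assumes exactly two clusters and
  that PC1 carries the structure.
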