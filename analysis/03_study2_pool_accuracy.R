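#!/usr/bin/env Rscript

# Step 3: how well do pooled-sample read counts estimate allele
# frequencies?
#
# The original sample's seven replicate DNA-pool libraries are filtered to
# the 10-126 reads-per-library window, merged by summing reads, and the
# pooled frequency estimates are compared with the individual-based ones,
# binned by merged read depth (the standard 10-49 ... >599 bins).

library(survscan)

data_dir <- file.path("results", "data")
if (!dir.exists(data_dir))
  stop("run analysis/01_simulate.R first (", data_dir, " is missing)")

g <- read_genotypes(file.path(data_dir, "study1_genotypes.tsv"), "tsv")
g_orig <- subset_genotypes(
  g, individuals = g$individuals$population_id == "original")
pool <- read_pool_counts(file.path(data_dir, "study2_pool_counts.tsv"))

out <- run_study2(g_orig, pool, filter_config(maf_scope = "all_samples"))

write.table(out$report, file.path("results", "study2_pool_accuracy.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

rep <- out$report[out$report$n_snps > 0, ]
message("pool-vs-individual accuracy by merged depth bin:")
for (i in seq_len(nrow(rep)))
  message(sprintf("  %4d-%4s reads: n=%4d  mean |dq| = %.3f  r^2 = %.2f",
                  rep$bin_lo[i],
                  ifelse(is.finite(rep$bin_hi[i]), rep$bin_hi[i], "inf"),
                  rep$n_snps[i], rep$mean_abs_deviation[i],
                  rep$r_squared[i]))
mid <- rep$bin_lo >= 100 & rep$bin_lo < 500
message(sprintf("overall at 100-499 reads: mean |dq| = %.3f",
                weighted.mean(rep$mean_abs_deviation[mid], rep$n_snps[mid])))
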