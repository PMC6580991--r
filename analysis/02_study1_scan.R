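#!/usr/bin/env Rscript

# Step 2: survivor-vs-original selection scan on individual genotypes.
#
# Call-level depth filtering, SNP selection (>= 25 genotyped individuals in
# every population, MAF > 0.05 in the original), gamete-count allele
# frequencies, per-SNP F_ST + 2N*F_ST chi-square against the original in
# each of the four survivor plots, the all-four intersection rule with the
# combined FDR l*P^n/d, Fisher exact confirmation, and a ranked report of
# the selected SNPs. Also writes the population-frequency PCA.

library(survscan)

data_dir <- file.path("results", "data")
if (!dir.exists(data_dir))
  stop("run analysis/01_simulate.R first (", data_dir, " is missing)")

g <- read_genotypes(file.path(data_dir, "study1_genotypes.tsv"), "tsv")
pops_tab <- read.table(file.path(data_dir, "study1_populations.tsv"),
                       header = TRUE, sep = "\t")
pops <- population_meta(pops_tab$population_id, pops_tab$role,
                        pops_tab$stand_type, pops_tab$seeding_density,
                        pops_tab$harvest_regime, pops_tab$replicate_plot,
                        pops_tab$n_sampled)

out <- run_study1(g, pops, verbose = TRUE)

write_scan_results(out$scan, file.path("results", "study1_scan.tsv"))
write.table(out$fdr, file.path("results", "study1_fdr.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(out$report, file.path("results", "study1_selected_snps.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write_pca(out$pca, file.path("results", "study1_population_pca.tsv"),
          ids = out$freq$populations)

truth <- read.table(file.path(data_dir, "truth.tsv"), header = TRUE)
hits <- out$report$snp_id
planted <- truth$snp_id[truth$selected]
message(sprintf("scan hits at P<0.1: %s", paste(hits, collapse = ", ")))
message(sprintf("%d of %d planted loci recovered; %d other hits",
                sum(planted %in% hits), length(planted),
                sum(!(hits %in% planted))))
message(sprintf("genome-wide mean F_ST across testable loci: %.4f",
                mean(out$scan$mean_fst[out$scan$testable], na.rm = TRUE)))
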