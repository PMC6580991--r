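#!/usr/bin/env Rscript

# Step 1: generate the synthetic field experiment all later steps analyse.
#
# One base population (two weakly diverged subpopulations, minor fraction
# 0.17), four replicate pure-stand survivor plots with five shared selected
# loci on top of heavy random mortality (500 of 2000 sown survive), GBS
# reads for the sampled individuals, seven replicate DNA-pool libraries of
# the original sample, and a study-3 layout of eight leaf-pool populations
# (pure/mixed stand x high/low seeding density) with four stand-specific
# and three density-specific selected loci.
#
# Writes all inputs in the package's file formats plus the simulator truth
# under results/data/.

library(survscan)

out_dir <- file.path("results", "data")

cfg <- sim_config(
  seed = 20190611, L = 2000, n_selected = 5,
  survival_probs = matrix(rep(c(0.1, 0.35, 1), each = 5), ncol = 3))

sim <- simulate_experiment(cfg, gbs_reads = TRUE, study3 = TRUE,
                           n_stand_loci = 4, n_density_loci = 3,
                           treatment_survival = c(0.08, 0.3, 1),
                           write_dir = out_dir)

dq <- abs(sim$truth$expected_q_selected - sim$truth$base_q[cfg$selected_loci])
message(sprintf("simulated %d loci; study-1 selected loci %s with expected |dq| %s",
                cfg$L, paste(cfg$selected_loci, collapse = ","),
                paste(round(dq, 2), collapse = ",")))
message(sprintf("study-3 stand-specific loci: %s; density-specific: %s",
                paste(sim$study3$stand_loci, collapse = ","),
                paste(sim$study3$density_loci, collapse = ",")))
message("wrote ", out_dir)
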