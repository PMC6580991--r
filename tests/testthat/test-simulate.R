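test_that("the simulator is deterministic given the config seed", {
  cfg <- sim_config(seed = 9, L = 120, n_selected = 2)
  a <- simulate_experiment(cfg, gbs_reads = TRUE, study3 = TRUE,
                           n_stand_loci = 2)
  b <- simulate_experiment(cfg, gbs_reads = TRUE, study3 = TRUE,
                           n_stand_loci = 2)
  expect_identical(a$study1$genotypes$dosage, b$study1$genotypes$dosage)
  expect_identical(a$study2$pool_counts$counts_alt,
                   b$study2$pool_counts$counts_alt)
  expect_identical(a$study3$pool_counts$counts_ref,
                   b$study3$pool_counts$counts_ref)
  expect_identical(a$truth$base_q, b$truth$base_q)
  c2 <- simulate_base_population(sim_config(seed = 9, L = 50), n = 30)
  c3 <- simulate_base_population(sim_config(seed = 9, L = 50), n = 30)
  expect_identical(c2$genotypes$dosage, c3$genotypes$dosage)
})

test_that("subpopulation divergence is calibrated and vanishes at F_ST 0", {
  cfg <- sim_config(seed = 10, L = 8000, fst0 = 0.02)
  tr <- draw_base_frequencies(cfg)
  realized <- mean(pairwise_fst(tr$sub_q[1, ], tr$sub_q[2, ]), na.rm = TRUE)
  expect_equal(realized, 0.02, tolerance = 0.15)
  cfg0 <- sim_config(seed = 10, L = 500, fst0 = 0)
  tr0 <- draw_base_frequencies(cfg0)
  expect_equal(tr0$sub_q[1, ], tr0$sub_q[2, ])
  expect_true(all(pmin(tr0$base_q, 1 - tr0$base_q) > 0.05))
})

test_that("genotypes are Hardy-Weinberg within subpopulation at large n", {
  cfg <- sim_config(seed = 12, L = 40, fst0 = 0)
  bp <- simulate_base_population(cfg, n = 10000, population_id = "big")
  q <- bp$truth$base_q
  counts <- vapply(0:2, function(d) colSums(bp$genotypes$dosage == d),
                   numeric(40))
  exp_p <- cbind((1 - q)^2, 2 * q * (1 - q), q^2)
  chi2 <- rowSums((counts - 10000 * exp_p)^2 / (10000 * exp_p))
  # 40 independent df-2 goodness-of-fit tests: none should be extreme
  expect_gt(min(pchisq(chi2, df = 2, lower.tail = FALSE)), 1e-4)
  expect_lt(mean(chi2), 2 + 3 * 2 / sqrt(40))
})

test_that("neutral survival is pure drift; selection follows the closed form", {
  cfg <- sim_config(seed = 13, L = 300, fst0 = 0, N_sown = 1000,
                    N_survivors = 400)
  set.seed(13)
  truth <- draw_base_frequencies(cfg)
  coh <- simulate_base_population(cfg, n = 1000, truth = truth,
                                  population_id = "c")$genotypes
  surv <- apply_viability_selection(coh, cfg)
  shift <- colMeans(surv$dosage) / 2 - colMeans(coh$dosage) / 2
  # mean neutral shift across 300 loci is 0 within Monte-Carlo error
  expect_lt(abs(mean(shift)), 3 * sd(shift) / sqrt(300))
  drift_sd <- sqrt(mean(truth$base_q * (1 - truth$base_q)) *
                     (1 / 800 - 1 / 2000))
  expect_lt(sd(shift), 4 * drift_sd)

  # single selected locus: mean post-selection q over replicate plots
  cfg1 <- sim_config(seed = 14, L = 1, fst0 = 0, N_sown = 1500,
                     N_survivors = 400, n_selected = 1,
                     survival_probs = matrix(c(0.5, 0.75, 1), 1))
  set.seed(14)
  q0 <- 0.35
  tr1 <- list(base_q = q0, sub_q = rbind(q0, q0), selected_loci = 1L,
              survival_probs = cfg1$survival_probs)
  qs <- replicate(300, {
    coh <- simulate_base_population(cfg1, n = 1500, truth = tr1,
                                    population_id = "c")$genotypes
    mean(apply_viability_selection(coh, cfg1)$dosage) / 2
  })
  q_exp <- expected_post_selection_q(q0, 0.5, 0.75, 1)
  expect_lt(abs(mean(qs) - q_exp), 3 * sd(qs) / sqrt(300))
})

test_that("survival probability scaling preserves the expected count", {
  set.seed(15)
  w <- rexp(1000)^2
  p <- survscan:::scale_survival_probs(w, 300)
  expect_equal(sum(p), 300, tolerance = 1e-9)
  expect_true(all(p >= 0 & p <= 1))
  # uncapped probabilities stay proportional to the weights
  un <- p < 1
  expect_lt(sd(p[un] / w[un]) / mean(p[un] / w[un]), 1e-10)
  expect_error(apply_viability_selection(
    genotype_matrix(snp_records("s1"),
                    data.frame(individual_id = "i", population_id = "p"),
                    matrix(2L), matrix(0L), matrix(20L)),
    sim_config(seed = 1, L = 1, n_selected = 1,
               survival_probs = matrix(c(0, 0, 0), 1)), 1), "all-zero")
})

test_that("GBS reads respect the error model and depth-driven missingness", {
  cfg0 <- sim_config(seed = 17, L = 60, fst0 = 0, seq_error = 0)
  bp <- simulate_base_population(cfg0, n = 40, population_id = "p")
  bp$genotypes$dosage[] <- 0L   # force hom-ref everywhere
  set.seed(117)
  reads <- simulate_gbs_reads(bp$genotypes, cfg0)
  expect_true(all(reads$depth_alt == 0))
  expect_true(all(reads$dosage %in% c(0L, NA)))

  cfg_low <- sim_config(seed = 18, L = 80, fst0 = 0, depth_mean = 1)
  bp2 <- simulate_base_population(cfg_low, n = 30, population_id = "p")
  set.seed(118)
  reads2 <- simulate_gbs_reads(bp2$genotypes, cfg_low)
  filtered <- filter_genotype_calls(reads2)
  expect_gt(mean(is.na(filtered$dosage)), 0.9)
})

test_that("allele frequencies from re-called reads are unbiased at depth 30", {
  cfg <- sim_config(seed = 19, L = 600, fst0 = 0, depth_mean = 30)
  bp <- simulate_base_population(cfg, n = 150, population_id = "p")
  set.seed(119)
  reads <- simulate_gbs_reads(bp$genotypes, cfg)
  f <- frequencies_from_genotypes(filter_genotype_calls(reads))
  true_q <- colMeans(bp$genotypes$dosage) / 2
  bias <- mean(f$q[1, ] - true_q, na.rm = TRUE)
  expect_lt(abs(bias), 0.005)
})

test_that("pooled reads reflect the sample frequency with mode-specific noise", {
  cfg <- sim_config(seed = 20, L = 400, fst0 = 0, seq_error = 0,
                    high_depth_cutoff = Inf)
  bp <- simulate_base_population(cfg, n = 100, population_id = "p")
  true_q <- colMeans(bp$genotypes$dosage) / 2
  set.seed(120)
  deep <- simulate_pool_reads(bp$genotypes, cfg, "dna_pool",
                              depth_mean = 50000, depth_dispersion = 1e9)
  q_deep <- deep$counts_alt[1, ] / pool_depth(deep)[1, ]
  expect_equal(unname(q_deep), unname(true_q), tolerance = 0.01)

  # leaf pools converge to DNA-pool behaviour as concentration grows
  cfg_inf <- cfg; cfg_inf$leaf_concentration <- 1e9
  set.seed(121)
  leaf_inf <- simulate_pool_reads(bp$genotypes, cfg_inf, "leaf_pool",
                                  n_replicates = 2, depth_mean = 400)
  set.seed(121)
  leaf_1 <- simulate_pool_reads(bp$genotypes, cfg, "leaf_pool",
                                n_replicates = 2, depth_mean = 400)
  dev_of <- function(p) {
    q <- p$counts_alt / pool_depth(p)
    mean(abs(q[1, ] - q[2, ]), na.rm = TRUE)
  }
  set.seed(122)
  dna <- simulate_pool_reads(bp$genotypes, cfg, "dna_pool",
                             n_replicates = 2, depth_mean = 400)
  expect_lt(dev_of(leaf_inf), dev_of(leaf_1))
  expect_equal(dev_of(leaf_inf), dev_of(dna), tolerance = 0.3)
  expect_error(simulate_pool_reads(bp$genotypes, cfg, "dna_pool",
                                   n_replicates = 0), ">= 1")
})

test_that("a simulated experiment round-trips through the file formats", {
  cfg <- sim_config(seed = 23, L = 60, n_selected = 3)
  dir <- withr::local_tempdir()
  sim <- simulate_experiment(cfg, gbs_reads = TRUE, study3 = TRUE,
                             n_stand_loci = 2, write_dir = dir)
  g <- read_genotypes(file.path(dir, "study1_genotypes.tsv"), "tsv")
  expect_equal(g$dosage, sim$study1$genotypes$dosage)
  p <- read_pool_counts(file.path(dir, "study2_pool_counts.tsv"))
  j <- match(sim$study2$pool_counts$snps$snp_id, p$snps$snp_id)
  expect_equal(unname(p$counts_alt[, j]),
               unname(sim$study2$pool_counts$counts_alt))
  truth <- utils::read.table(file.path(dir, "truth.tsv"), header = TRUE)
  expect_equal(truth$selected, seq_len(60) %in% 1:3)
  expect_equal(truth$base_q, sim$truth$base_q, tolerance = 1e-12)
})
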