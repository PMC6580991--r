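test_that("per-call depth rules match the stated boundaries", {
  snps <- snp_records(c("a", "b", "c"))
  ind <- data.frame(individual_id = "i1", population_id = "p1")
  g <- genotype_matrix(snps, ind,
                       dosage = matrix(c(1L, 0L, 1L), 1),
                       depth_ref = matrix(c(1L, 10L, 2L), 1),
                       depth_alt = matrix(c(12L, 0L, 8L), 1))
  out <- filter_genotype_calls(g)
  expect_true(is.na(out$dosage[1, "a"]))   # het with one allele read once
  expect_equal(unname(out$dosage[1, "b"]), 0L)  # hom at exactly 10 reads
  expect_equal(unname(out$dosage[1, "c"]), 1L)  # het at (2, 8)
  expect_equal(out$depth_alt, g$depth_alt)     # depths untouched
})

test_that("call filter equals the brute-force rule over all depth pairs <= 15", {
  grid <- expand.grid(dosage = c(0L, 1L, 2L, NA), dref = 0:15, dalt = 0:15)
  snps <- snp_records(paste0("s", seq_len(nrow(grid))))
  ind <- data.frame(individual_id = "i1", population_id = "p1")
  g <- genotype_matrix(snps, ind,
                       dosage = matrix(grid$dosage, 1),
                       depth_ref = matrix(grid$dref, 1),
                       depth_alt = matrix(grid$dalt, 1))
  out <- filter_genotype_calls(g)
  expected <- mapply(function(d, r, a) {
    ok <- oracle_call_ok(d, r, a)
    if (is.na(ok) || !ok) NA_integer_ else d
  }, grid$dosage, grid$dref, grid$dalt)
  expect_equal(unname(out$dosage[1, ]), unname(expected))
})

test_that("SNP selection enforces the per-population count and strict MAF rule", {
  set.seed(11)
  n_per <- 30
  ind <- data.frame(
    individual_id = paste0("i", 1:(2 * n_per)),
    population_id = rep(c("orig", "sv1"), each = n_per))
  snps <- snp_records(c("low_n", "maf_at_threshold", "good"))
  dos <- cbind(
    c(rep(1L, 24), rep(NA, 6), rep(1L, n_per)),       # 24 < 25 in orig
    c(rep(0L, 27), rep(1L, 3), rep(1L, n_per)),       # orig MAF = 3/60 = 0.05
    c(rep(0L, 20), rep(1L, 10), rep(1L, n_per)))      # orig MAF = 10/60
  g <- genotype_matrix(snps, ind, dos,
                       matrix(10L, 2 * n_per, 3), matrix(10L, 2 * n_per, 3))
  pops <- population_meta(c("orig", "sv1"), c("original", "survivor"),
                          n_sampled = n_per)
  kept <- select_snps_individuals(g, pops, filter_config())
  expect_equal(kept$snp_id, "good")
})

test_that("SNP selection equals a brute-force oracle on random fixtures", {
  for (seed in 1:3) {
    g <- random_genotypes(80, 50, n_pop = 3, seed = seed, depth_mean = 14)
    g <- filter_genotype_calls(g)
    pops <- population_meta(paste0("pop", 1:3),
                            c("original", "survivor", "survivor"),
                            n_sampled = 27)
    kept <- select_snps_individuals(
      g, pops, filter_config(min_genotyped_per_pop = 20L))
    expect_equal(kept$snp_id,
                 oracle_select_individuals(g, "pop1", min_geno = 20))
  }
})

test_that("pool depth windows are inclusive and applied per sample", {
  snps <- snp_records(c("low", "edge_max", "ok"))
  pools <- data.frame(pool_id = paste0("p", 1:12),
                      population_id = paste0("p", 1:12),
                      replicate_index = 1:12,
                      library_id = paste0("l", 1:12))
  depth <- matrix(200L, 12, 3)
  depth[7, 1] <- 99L                 # one sample below a 100-499 window
  cr <- depth; cr[] <- as.integer(round(depth * 0.6))
  ca <- depth - cr
  # edge case: depth exactly at the inclusive max of a 10-126 window
  p126 <- pool_count_table(pools[1, ], snps[2, , drop = FALSE],
                           matrix(76L, 1), matrix(50L, 1))
  kept126 <- select_snps_pools(p126, filter_config(pool_depth_min = 10L,
                                                   pool_depth_max = 126L),
                               scope = "per_library")
  expect_equal(kept126$snp_id, "edge_max")

  p <- pool_count_table(pools, snps, cr, ca)
  kept <- select_snps_pools(p, filter_config(pool_depth_min = 100L,
                                             pool_depth_max = 499L),
                            scope = "all_samples")
  expect_false("low" %in% kept$snp_id)
  expect_true(all(c("edge_max", "ok") %in% kept$snp_id))
})

test_that("pool selection equals the brute-force oracle, with and without MAF", {
  for (seed in 4:6) {
    p <- random_pool_table(6, 60, seed = seed, depth_mean = 70)
    cfg <- filter_config(pool_depth_min = 40L, pool_depth_max = 100L,
                         maf_threshold = 0.05)
    expect_equal(select_snps_pools(p, cfg, "per_library")$snp_id,
                 oracle_select_pools(p, 40, 100))
    expect_equal(select_snps_pools(p, cfg, "all_samples")$snp_id,
                 oracle_select_pools(p, 40, 100, maf_thr = 0.05))
  }
})

test_that("after_merge scope filters on summed library depth", {
  pools <- data.frame(pool_id = c("A", "A", "B"),
                      population_id = c("A", "A", "B"),
                      replicate_index = c(1L, 2L, 1L),
                      library_id = c("l1", "l2", "l3"))
  snps <- snp_records(c("s1", "s2"))
  cr <- rbind(c(30L, 5L), c(35L, 5L), c(60L, 200L))
  ca <- rbind(c(30L, 5L), c(35L, 5L), c(60L, 100L))
  p <- pool_count_table(pools, snps, cr, ca)
  kept <- select_snps_pools(p, filter_config(pool_depth_min = 100L,
                                             pool_depth_max = 499L),
                            scope = "after_merge")
  expect_equal(kept$snp_id, "s1")   # pool A sums 130, pool B 120; s2: A = 20
})

test_that("chromosomal-only restriction drops scaffold SNPs", {
  p <- random_pool_table(3, 40, seed = 8)
  cfg <- filter_config(pool_depth_min = 1L, pool_depth_max = 10000L)
  kept <- select_snps_pools(p, cfg, "per_library", chromosomal_only = TRUE)
  expect_true(all(!is.na(kept$chrom)))
  expect_equal(kept$snp_id,
               intersect(oracle_select_pools(p, 1, 10000),
                         p$snps$snp_id[!is.na(p$snps$chrom)]))
})

test_that("filters are monotone in their thresholds and idempotent", {
  g <- random_genotypes(40, 60, seed = 21, depth_mean = 11)
  kept_calls <- function(min_total) {
    sum(!is.na(filter_genotype_calls(
      g, filter_config(min_total_reads = min_total))$dosage))
  }
  counts <- vapply(c(0L, 5L, 10L, 15L, 20L), kept_calls, 0)
  expect_true(all(diff(counts) <= 0))

  f1 <- filter_genotype_calls(g)
  expect_identical(filter_genotype_calls(f1), f1)

  p <- random_pool_table(4, 80, seed = 22, depth_mean = 60)
  n_kept <- function(lo, hi)
    nrow(select_snps_pools(p, filter_config(pool_depth_min = lo,
                                            pool_depth_max = hi),
                           "per_library"))
  expect_true(n_kept(40L, 90L) <= n_kept(30L, 100L))
  expect_true(n_kept(30L, 100L) <= n_kept(10L, 200L))
})
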