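test_that("pairwise F_ST matches hand values and stays in bounds", {
  expect_equal(pairwise_fst(0.3, 0.3), 0)
  expect_equal(pairwise_fst(0, 1), 1)
  expect_equal(pairwise_fst(0.2, 0.4), 0.2^2 / (4 * 0.3 * 0.7))
  expect_equal(round(pairwise_fst(0.2, 0.4), 6), 0.047619)
  # the published worked pair: 0.46 vs 0.68 rounds to 0.049
  expect_equal(round(pairwise_fst(0.46, 0.68), 4), 0.0494)
  expect_equal(round(pairwise_fst(0.46, 0.68), 2),
               round(pairwise_fst(0.68, 0.46), 2))
  expect_true(is.na(pairwise_fst(0, 0)))
  expect_true(is.na(pairwise_fst(1, 1)))
})

test_that("F_ST equals the two-population variance form", {
  set.seed(77)
  q1 <- runif(1e5); q2 <- runif(1e5)
  qbar <- (q1 + q2) / 2
  variance_form <- ((q1^2 + q2^2) / 2 - qbar^2) / (qbar * (1 - qbar))
  got <- pairwise_fst(q1, q2)
  ok <- !is.na(got)
  expect_equal(got[ok], variance_form[ok], tolerance = 1e-12)
  expect_true(all(got[ok] >= 0 & got[ok] <= 1 + 1e-12))
})

test_that("the 2N*F_ST chi-square test behaves as a df-1 upper tail", {
  expect_equal(fst_chi2_test(0, 200)$p, 1)
  t1 <- fst_chi2_test(0.047619, 200)
  expect_equal(t1$statistic, 9.5238, tolerance = 1e-4)
  expect_equal(t1$p, 0.002028, tolerance = 1e-3)
  # p strictly decreasing in the gamete count at fixed positive F_ST
  ps <- fst_chi2_test(0.02, c(100, 200, 400, 800))$p
  expect_true(all(diff(ps) < 0))
  expect_true(is.na(fst_chi2_test(NA_real_, 100)$p))
})

test_that("combined FDR reproduces the published values and conventions", {
  expect_equal(round(combined_fdr(4966, 0.1, 4, 27)$fdr, 3), 0.018)
  expect_equal(round(combined_fdr(4966, 0.05, 4, 13)$fdr, 3), 0.002)
  expect_equal(round(combined_fdr(4556, 0.1, 4, 11)$fdr, 2), 0.04)
  expect_equal(round(combined_fdr(4556, 0.05, 4, 6)$fdr, 3), 0.005)
  expect_equal(signif(combined_fdr(4556, 0.01, 4, 1)$fdr, 1), 5e-5)
  expect_true(is.na(combined_fdr(100, 0.05, 4, 0)$fdr))
  # decreasing in d at fixed l, P, n
  fdrs <- vapply(1:10, function(d) combined_fdr(1000, 0.1, 4, d)$fdr, 0)
  expect_true(all(diff(fdrs) < 0))
})

test_that("Fisher confirmation equals the hypergeometric enumeration oracle", {
  expect_equal(fisher_confirm(10, 10, 10, 10), 1)
  expect_equal(fisher_confirm(20, 0, 10, 10), oracle_fisher(20, 0, 10, 10))
  expect_equal(fisher_confirm(20, 0, 10, 10), 0.000436, tolerance = 1e-3)
  # empty margin convention
  expect_equal(fisher_confirm(0, 0, 5, 5), 1)
  set.seed(99)
  for (i in 1:40) {
    cnt <- rpois(4, lambda = sample(c(3, 15, 60), 1))
    expect_equal(fisher_confirm(cnt[1], cnt[2], cnt[3], cnt[4]),
                 oracle_fisher(cnt[1], cnt[2], cnt[3], cnt[4]),
                 tolerance = 1e-10)
  }
  # two-sided p is at least the one-sided tail
  one_sided <- sum(dhyper(20:20, 30, 10, 20))
  expect_gte(fisher_confirm(20, 0, 10, 10), one_sided)
})

test_that("intersection rule requires significance in every comparison", {
  # 3 of 4 survivor populations significant: not selected
  snps <- snp_records(c("three_of_four", "all_four"))
  q <- rbind(orig = c(0.10, 0.10),
             s1 = c(0.30, 0.30), s2 = c(0.30, 0.30),
             s3 = c(0.30, 0.30), s4 = c(0.12, 0.30))
  two_n <- matrix(rep(c(160, 100, 100, 100, 100), 2), 5, 2)
  f <- freq_table(snps, rownames(q), q, two_n)
  scan <- intersection_scan(f, scan_config(ref_population = "orig"))
  # per-pair check, by hand: fst(0.1, 0.3) at 2N = 260 is significant
  expect_lt(fst_chi2_test(pairwise_fst(0.1, 0.3), 260)$p, 0.05)
  expect_gt(fst_chi2_test(pairwise_fst(0.1, 0.12), 260)$p, 0.05)
  expect_false(scan$selected["three_of_four", "P0.05"])
  expect_true(scan$selected["all_four", "P0.05"])
  expect_equal(scan$l, 2)
})

test_that("selection flags are monotone across nested levels", {
  set.seed(55)
  f <- freq_table(snp_records(paste0("s", 1:300)),
                  c("orig", paste0("sv", 1:4)),
                  q = matrix(runif(1500, 0.05, 0.95), 5, 300),
                  two_n = matrix(sample(c(96, 120, 176), 1500, TRUE), 5, 300))
  scan <- intersection_scan(
    f, scan_config(alpha_levels = c(0.2, 0.1, 0.05, 0.01),
                   ref_population = "orig"))
  sel <- scan$selected
  for (i in seq_len(ncol(sel) - 1))
    expect_true(all(sel[, i + 1] <= sel[, i]))
  # untested SNPs are excluded from l
  f$q["sv2", 7] <- NA
  scan2 <- intersection_scan(f, scan_config(ref_population = "orig"))
  expect_equal(scan2$l, 299)
  expect_false(scan2$selected[7, 1])
})

test_that("group-mean mode compares against the opposite group's pooled mean", {
  snps <- snp_records("s1")
  pops <- c("Ps1", "Ps2", "Ps3", "Ps4", "Ms1", "Ms2", "Ms3", "Ms4")
  q <- matrix(c(0.62, 0.60, 0.58, 0.60, 0.30, 0.28, 0.32, 0.30), 8, 1,
              dimnames = list(pops, "s1"))
  f <- freq_table(snps, pops, q, matrix(200, 8, 1))
  groups <- setNames(rep(c("pure", "mixed"), each = 4), pops)
  scan <- intersection_scan(
    f, scan_config(comparison_mode = "vs_opposite_group_mean",
                   groups = groups))
  expect_equal(length(scan$comparisons), 8)
  expect_equal(scan$n_independent, 4)
  # first comparison by hand: Ps1 vs the Ms mean with summed gametes
  ms_mean <- mean(c(0.30, 0.28, 0.32, 0.30))
  fst_hand <- pairwise_fst(0.62, ms_mean)
  expect_equal(unname(scan$fst["s1", 1]), fst_hand)
  expect_equal(unname(scan$chi2["s1", 1]), (200 + 800) * fst_hand)
  expect_true(scan$selected["s1", "P0.05"])
  expect_true(scan$dir_consistent["s1"])
})

test_that("FDR summary counts d per level from the scan", {
  set.seed(60)
  f <- freq_table(snp_records(paste0("s", 1:200)),
                  c("orig", paste0("sv", 1:4)),
                  q = matrix(runif(1000, 0.05, 0.95), 5, 200),
                  two_n = matrix(150, 5, 200))
  scan <- intersection_scan(f, scan_config(ref_population = "orig"))
  fs <- fdr_summary(scan)
  expect_equal(fs$d, unname(colSums(scan$selected)))
  expect_equal(fs$l, rep(scan$l, 3))
  expect_equal(fs$fdr, ifelse(fs$d > 0, fs$l * fs$P^4 / fs$d, NA))
})

test_that("scan report ranks by frequency change and computes errors", {
  snps <- snp_records(c("big", "small"), chrom = c("Tp3", NA),
                      pos = c(5909984L, NA))
  # the published worked row: 0.46 in the original, survivors averaging 0.68
  q <- rbind(orig = c(0.46, 0.20),
             s1 = c(0.66, 0.34), s2 = c(0.67, 0.35),
             s3 = c(0.69, 0.36), s4 = c(0.70, 0.35))
  two_n <- matrix(rep(c(78, 54, 60, 66, 70), 2), 5, 2)
  f <- freq_table(snps, rownames(q), q, two_n)
  scan <- intersection_scan(f, scan_config(ref_population = "orig"))
  rep_tab <- summarize_scan(scan, f, level = 0.1, ref_population = "orig")
  expect_equal(rep_tab$snp_id, c("big", "small"))  # sorted by |delta q|
  big <- rep_tab[1, ]
  expect_equal(big$q_ref, 0.46)
  expect_equal(big$mean_q, 0.68)
  expect_equal(big$abs_delta_q, 0.22)
  expect_equal(big$two_n_min, 54)
  expect_equal(big$two_n_max, 70)
  # s.e. of the mean F_ST over 4 comparisons is the sample s.d. / 2
  fst_row <- scan$fst["big", ]
  expect_equal(big$se_fst, sd(fst_row) / 2)
  expect_equal(big$se_q, sd(q[-1, 1]) / 2)

  # empty selected set: empty report, d = 0, FDR NA
  f2 <- freq_table(snps, rownames(q),
                   q = matrix(0.3, 5, 2), two_n = two_n)
  scan2 <- intersection_scan(f2, scan_config(ref_population = "orig"))
  expect_equal(nrow(summarize_scan(scan2, f2, ref_population = "orig")), 0)
  fs2 <- fdr_summary(scan2)
  expect_equal(fs2$d, rep(0L, 3))
  expect_true(all(is.na(fs2$fdr)))
})

test_that("scan configuration is validated", {
  expect_error(scan_config(ref_population = NULL), "ref_population")
  expect_error(scan_config(comparison_mode = "vs_opposite_group_mean",
                           groups = c(a = "x")), "two levels")
  expect_error(scan_config(alpha_levels = c(0.5, 1.2),
                           ref_population = "o"))
  f <- freq_table(snp_records("s1"), c("orig", "sv1"),
                  matrix(0.4, 2, 1), matrix(100, 2, 1))
  expect_error(intersection_scan(f, scan_config(ref_population = "orig")),
               "at least 2")
})
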