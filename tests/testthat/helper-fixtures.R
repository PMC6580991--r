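# Fixture builders and independent brute-force oracles used across tests.

# small genotype matrix with explicit values
tiny_genotypes <- function() {
  snps <- data.frame(snp_id = c("s1", "s2", "s3"),
                     chrom = c("Tp1", NA, "Tp3"),
                     pos = c(100L, NA, 5909984L),
                     ref = "A", alt = "C", stringsAsFactors = FALSE)
  ind <- data.frame(individual_id = c("i1", "i2"),
                    population_id = c("orig", "surv"),
                    stringsAsFactors = FALSE)
  genotype_matrix(snps, ind,
                  dosage = rbind(c(0L, 1L, NA), c(2L, 1L, 0L)),
                  depth_ref = rbind(c(10L, 4L, 3L), c(0L, 6L, 12L)),
                  depth_alt = rbind(c(0L, 6L, 0L), c(11L, 5L, 0L)))
}

# random genotype matrix; dosages consistent-ish with depths
random_genotypes <- function(n_ind, n_snp, n_pop = 2, seed = 1,
                             depth_mean = 12) {
  set.seed(seed)
  snps <- data.frame(snp_id = paste0("s", seq_len(n_snp)),
                     chrom = sample(c("Tp1", "Tp2", NA), n_snp, TRUE),
                     pos = sample.int(1e6, n_snp), ref = "A", alt = "G",
                     stringsAsFactors = FALSE)
  ind <- data.frame(individual_id = paste0("i", seq_len(n_ind)),
                    population_id = paste0("pop",
                                           rep_len(seq_len(n_pop), n_ind)),
                    stringsAsFactors = FALSE)
  q <- runif(n_snp, 0.05, 0.95)
  dosage <- matrix(rbinom(n_ind * n_snp, 2, rep(q, each = n_ind)),
                   n_ind, n_snp)
  depth <- matrix(rpois(n_ind * n_snp, depth_mean), n_ind, n_snp)
  alt <- matrix(rbinom(n_ind * n_snp, depth, dosage / 2), n_ind, n_snp)
  dosage[depth == 0] <- NA
  genotype_matrix(snps, ind, dosage, depth - alt, alt)
}

random_pool_table <- function(n_lib, n_snp, seed = 1, depth_mean = 60,
                              pool_ids = paste0("pool", seq_len(n_lib))) {
  set.seed(seed)
  snps <- data.frame(snp_id = paste0("s", seq_len(n_snp)),
                     chrom = sample(c("Tp1", NA), n_snp, TRUE),
                     pos = sample.int(1e6, n_snp), ref = "A", alt = "G",
                     stringsAsFactors = FALSE)
  pools <- data.frame(pool_id = pool_ids,
                      population_id = pool_ids,
                      replicate_index = seq_len(n_lib),
                      library_id = paste0("lib", seq_len(n_lib)),
                      stringsAsFactors = FALSE)
  depth <- matrix(rpois(n_lib * n_snp, depth_mean), n_lib, n_snp)
  alt <- matrix(rbinom(n_lib * n_snp, depth, 0.4), n_lib, n_snp)
  pool_count_table(pools, snps, depth - alt, alt)
}

# --- oracles ------------------------------------------------------------

# per-call depth rule, one call at a time
oracle_call_ok <- function(dosage, dref, dalt, min_total = 10, min_het = 2) {
  if (is.na(dosage)) return(NA)
  if (dref + dalt < min_total) return(FALSE)
  if (dosage == 1 && (dref < min_het || dalt < min_het)) return(FALSE)
  TRUE
}

# SNP retention for individual data, loops over everything
oracle_select_individuals <- function(g, orig_pop, min_geno = 25,
                                      maf_thr = 0.05) {
  keep <- logical(ncol(g$dosage))
  for (j in seq_len(ncol(g$dosage))) {
    ok <- TRUE
    for (p in unique(g$individuals$population_id)) {
      rows <- g$individuals$population_id == p
      if (sum(!is.na(g$dosage[rows, j])) < min_geno) ok <- FALSE
    }
    rows <- g$individuals$population_id %in% orig_pop
    d <- g$dosage[rows, j]
    n <- sum(!is.na(d))
    if (n == 0) ok <- FALSE else {
      q <- sum(d, na.rm = TRUE) / (2 * n)
      if (min(q, 1 - q) <= maf_thr) ok <- FALSE
    }
    keep[j] <- ok
  }
  g$snps$snp_id[keep]
}

# pool SNP retention, loops over libraries
oracle_select_pools <- function(p, dmin, dmax, maf_thr = NULL) {
  keep <- logical(nrow(p$snps))
  for (j in seq_len(nrow(p$snps))) {
    ok <- TRUE
    for (i in seq_len(nrow(p$pools))) {
      d <- p$counts_ref[i, j] + p$counts_alt[i, j]
      if (d < dmin || d > dmax) ok <- FALSE
      if (!is.null(maf_thr)) {
        if (d == 0) ok <- FALSE else {
          q <- p$counts_alt[i, j] / d
          if (min(q, 1 - q) <= maf_thr) ok <- FALSE
        }
      }
    }
    keep[j] <- ok
  }
  p$snps$snp_id[keep]
}

# two-sided Fisher exact by full hypergeometric enumeration
oracle_fisher <- function(alt1, ref1, alt2, ref2) {
  m <- alt1 + alt2; n <- ref1 + ref2; k <- alt1 + ref1
  if (m == 0 || n == 0 || k == 0 || k == m + n) return(1)
  xs <- max(0, k - n):min(k, m)
  ps <- dhyper(xs, m, n, k)
  p_obs <- dhyper(alt1, m, n, k)
  sum(ps[ps <= p_obs * (1 + 1e-7)])
}

# balanced two-way ANOVA by explicit cell-mean decomposition
oracle_anova <- function(y, stand, density) {
  g <- mean(y)
  lev_s <- unique(stand); lev_d <- unique(density)
  r <- length(y) / 4
  a <- vapply(lev_s, function(s) mean(y[stand == s]), 0)
  b <- vapply(lev_d, function(d) mean(y[density == d]), 0)
  ss_a <- 2 * r * sum((a - g)^2)
  ss_b <- 2 * r * sum((b - g)^2)
  cell <- outer(lev_s, lev_d, Vectorize(function(s, d)
    mean(y[stand == s & density == d])))
  ss_ab <- r * sum((sweep(sweep(cell, 1, a - g), 2, b - g) - g)^2)
  ss_tot <- sum((y - g)^2)
  list(ss_stand = ss_a, ss_density = ss_b, ss_interaction = ss_ab,
       ss_error = ss_tot - ss_a - ss_b - ss_ab)
}

# brute-force optimal 2-means over all 2^n assignments (tiny n)
oracle_2means_ss <- function(x) {
  n <- length(x)
  best <- Inf
  for (code in 1:(2^n - 2)) {
    lab <- as.logical(bitwAnd(code, 2^(0:(n - 1))))
    ss <- sum((x[lab] - mean(x[lab]))^2) +
      sum((x[!lab] - mean(x[!lab]))^2)
    best <- min(best, ss)
  }
  best
}

within_ss <- function(x, lab) {
  sum(tapply(x, lab, function(v) sum((v - mean(v))^2)))
}
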