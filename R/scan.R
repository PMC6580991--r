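#' Two-population F_ST for one SNP
#'
#' The between-population variance of the allele frequency over
#' `qbar * (1 - qbar)` with `qbar = (q1 + q2) / 2`; for two populations this
#' is algebraically `(q1 - q2)^2 / (4 * qbar * (1 - qbar))`. Symmetric in
#' its arguments, bounded in [0, 1]. Returns `NA` where `qbar` is 0 or 1
#' (monomorphic pair; excluded upstream by the MAF filter). Vectorized.
#'
#' @param q1,q2 allele frequencies in [0, 1]
#' @return F_ST value(s) in [0, 1], NA for monomorphic pairs
#' @export
pairwise_fst <- function(q1, q2) {
  stopifnot(all(q1 >= 0 & q1 <= 1, na.rm = TRUE),
            all(q2 >= 0 & q2 <= 1, na.rm = TRUE))
  qbar <- (q1 + q2) / 2
  denom <- 4 * qbar * (1 - qbar)
  ifelse(is.na(denom) | denom <= 0, NA_real_, (q1 - q2)^2 / denom)
}

#' Chi-square test of an F_ST value
#'
#' Test statistic `X2 = 2N * F_ST`, where `2N` is the sum of genotyped
#' gametes in the two populations compared; p is the upper tail of the
#' chi-square distribution with 1 degree of freedom (biallelic SNP).
#' Vectorized.
#'
#' @param fst F_ST value(s)
#' @param two_n_total total gamete count(s) of the two populations
#' @return list with `statistic` and `p`
#' @export
fst_chi2_test <- function(fst, two_n_total) {
  stopifnot(all(two_n_total > 0, na.rm = TRUE))
  stat <- two_n_total * fst
  list(statistic = stat,
       p = ifelse(is.na(stat), NA_real_,
                  stats::pchisq(stat, df = 1, lower.tail = FALSE)))
}

#' Scan configuration
#'
#' @param alpha_levels per-test significance levels P, default
#'   `c(0.1, 0.05, 0.01)`.
#' @param comparison_mode "vs_original": each survivor population against
#'   the reference population; "vs_opposite_group_mean": each population
#'   against the unweighted mean frequency of the opposite treatment group.
#' @param ref_population id of the original population (vs_original mode).
#' @param groups named character vector population id -> group label
#'   (vs_opposite_group_mean mode; exactly two groups).
#' @param n_independent the `n` used in the combined FDR. Defaults to the
#'   number of comparisons in vs_original mode and to half the number of
#'   populations in vs_opposite_group_mean mode (8 F_ST values but only 4
#'   independent ones).
#' @param require_all number of comparisons that must be significant;
#'   default all of them.
#' @return list of class `scan_config`
#' @export
scan_config <- function(alpha_levels = c(0.1, 0.05, 0.01),
                        comparison_mode = c("vs_original",
                                            "vs_opposite_group_mean"),
                        ref_population = NULL, groups = NULL,
                        n_independent = NULL, require_all = NULL) {
  comparison_mode <- match.arg(comparison_mode)
  stopifnot(all(alpha_levels > 0 & alpha_levels < 1))
  if (comparison_mode == "vs_original" && is.null(ref_population))
    stop("vs_original mode needs ref_population")
  if (comparison_mode == "vs_opposite_group_mean") {
    if (is.null(groups) || length(unique(groups)) != 2)
      stop("vs_opposite_group_mean mode needs 'groups' with exactly two levels")
  }
  structure(list(alpha_levels = sort(alpha_levels, decreasing = TRUE),
                 comparison_mode = comparison_mode,
                 ref_population = ref_population, groups = groups,
                 n_independent = n_independent, require_all = require_all),
            class = "scan_config")
}

#' Replicate-intersection selection scan
#'
#' For every SNP computes the per-comparison F_ST and its `2N * F_ST`
#' chi-square p-value, then flags a SNP as selected at level P only if ALL
#' required comparisons are individually significant (p < P). A SNP with a
#' missing frequency or monomorphic pair in any comparison is untested and
#' excluded from the count `l` of loci tested. Direction consistency of the
#' frequency shift across replicates is recorded but not required.
#'
#' In `vs_opposite_group_mean` mode each population is compared with the
#' unweighted mean frequency of the other group; that mean carries the sum
#' of its member populations' gamete counts.
#'
#' @param f freq_table (polarized; same tracked allele in all populations)
#' @param cfg scan_config
#' @return object of class `scan_result`
#' @export
intersection_scan <- function(f, cfg) {
  pops <- f$populations
  if (cfg$comparison_mode == "vs_original") {
    if (!cfg$ref_population %in% pops)
      stop("ref_population not in frequency table")
    focal <- setdiff(pops, cfg$ref_population)
    if (length(focal) < 2)
      stop("intersection scan needs at least 2 survivor populations")
    q_a <- f$q[focal, , drop = FALSE]
    n_a <- f$two_n[focal, , drop = FALSE]
    q_b <- matrix(f$q[cfg$ref_population, ], length(focal), ncol(f$q),
                  byrow = TRUE)
    n_b <- matrix(f$two_n[cfg$ref_population, ], length(focal), ncol(f$q),
                  byrow = TRUE)
    comp_names <- paste0(focal, "_vs_", cfg$ref_population)
    comp_group <- rep("survivor", length(focal))
    n_indep <- if (is.null(cfg$n_independent)) length(focal) else
      cfg$n_independent
  } else {
    groups <- cfg$groups
    if (!all(pops %in% names(groups)))
      stop("missing treatment metadata: every population needs a group")
    g_of <- groups[pops]
    lev <- unique(unname(g_of))
    focal <- pops
    q_a <- f$q
    n_a <- f$two_n
    q_b <- matrix(NA_real_, length(pops), ncol(f$q))
    n_b <- q_b
    for (i in seq_along(pops)) {
      opp <- pops[g_of != g_of[i]]
      q_b[i, ] <- colMeans(f$q[opp, , drop = FALSE])          # NA propagates
      n_b[i, ] <- colSums(f$two_n[opp, , drop = FALSE])
    }
    comp_names <- paste0(pops, "_vs_mean_",
                         ifelse(g_of == lev[1], lev[2], lev[1]))
    comp_group <- unname(g_of)
    n_indep <- if (is.null(cfg$n_independent)) length(pops) / 2 else
      cfg$n_independent
  }
  fst <- pairwise_fst(q_a, q_b)
  test <- fst_chi2_test(fst, pmax(n_a + n_b, 1))
  p <- test$p
  p[n_a + n_b <= 0] <- NA_real_

  k <- nrow(q_a)
  require_all <- if (is.null(cfg$require_all)) k else cfg$require_all
  testable <- colSums(!is.na(p)) == k
  levels <- cfg$alpha_levels
  selected <- vapply(levels, function(P) {
    testable & colSums(p < P, na.rm = TRUE) >= require_all
  }, logical(ncol(p)))
  selected <- matrix(selected, ncol = length(levels),
                     dimnames = list(colnames(f$q),
                                     paste0("P", levels)))
  shift <- q_a - q_b
  sgn <- sign(shift)
  if (ncol(sgn) == 0) {
    dir_consistent <- logical(0)
    se_fst <- numeric(0)
  } else if (cfg$comparison_mode == "vs_original") {
    dir_consistent <- apply(sgn, 2, function(s)
      !anyNA(s) && (all(s >= 0) || all(s <= 0)))
    se_fst <- apply(fst, 2, stats::sd) / sqrt(k)
  } else {
    ga <- comp_group == comp_group[1]
    dir_consistent <- apply(sgn, 2, function(s)
      !anyNA(s) && ((all(s[ga] >= 0) && all(s[!ga] <= 0)) ||
                      (all(s[ga] <= 0) && all(s[!ga] >= 0))))
    se_fst <- apply(fst, 2, stats::sd) / sqrt(k)
  }
  structure(list(
    snps = f$snps, comparisons = comp_names, comparison_group = comp_group,
    fst = t(fst), chi2 = t(test$statistic), p = t(p),
    q_focal = t(q_a), q_ref = t(q_b),
    selected = selected, testable = testable,
    mean_fst = colMeans(fst), se_fst = se_fst,
    mean_abs_shift = colMeans(abs(shift)),
    mean_shift = colMeans(shift),
    dir_consistent = dir_consistent,
    fisher_p = rep(NA_real_, ncol(f$q)),
    levels = levels, mode = cfg$comparison_mode,
    n_independent = n_indep, l = sum(testable)
  ), class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> %d SNPs (%d testable), %d comparisons (%s)\n",
              nrow(x$snps), x$l, length(x$comparisons), x$mode))
  for (i in seq_along(x$levels))
    cat(sprintf("  P < %-5g : d = %d\n", x$levels[i],
                sum(x$selected[, i])))
  invisible(x)
}

#' Flatten a scan result to one row per SNP
#' @param x scan_result
#' @param ... unused
#' @return data.frame
#' @export
as.data.frame.scan_result <- function(x, ...) {
  df <- data.frame(snp_id = x$snps$snp_id,
                   chrom = x$snps$chrom, pos = x$snps$pos,
                   testable = x$testable,
                   mean_fst = x$mean_fst, se_fst = x$se_fst,
                   mean_abs_shift = x$mean_abs_shift,
                   mean_shift = x$mean_shift,
                   dir_consistent = x$dir_consistent,
                   fisher_p = x$fisher_p,
                   stringsAsFactors = FALSE)
  fst <- x$fst; colnames(fst) <- paste0("fst.", x$comparisons)
  p <- x$p; colnames(p) <- paste0("p.", x$comparisons)
  sel <- x$selected * 1L
  colnames(sel) <- paste0("selected.", colnames(x$selected))
  cbind(df, fst, p, sel)
}

#' Combined false-discovery-rate estimate for the intersection rule
#'
#' `FDR = l * P^n / d`: the number of loci expected to pass the
#' intersection rule by chance (`l` tested loci, each passing `n`
#' independent tests at level `P` with probability `P^n`) divided by the
#' number `d` observed to pass. `NA` when `d = 0`.
#'
#' @param l number of SNP loci tested
#' @param P per-test significance level
#' @param n number of independent comparisons
#' @param d loci significant in all comparisons
#' @return one-row data.frame of class `fdr_estimate`: P, l, n, d, fdr
#' @export
combined_fdr <- function(l, P, n, d) {
  stopifnot(l >= 1, P > 0, P < 1, n >= 1, d >= 0)
  out <- data.frame(P = P, l = l, n = n, d = d,
                    fdr = ifelse(d > 0, l * P^n / d, NA_real_))
  class(out) <- c("fdr_estimate", "data.frame")
  out
}

#' Fisher exact confirmation of an allele-frequency difference
#'
#' Two-sided exact p for a 2x2 allele-count table (sum over all tables, at
#' fixed margins, whose hypergeometric probability does not exceed the
#' observed table's). Used to confirm intersection hits by comparing the
#' combined survivor gamete counts with the original population's. An
#' empty margin gives p = 1. Vectorized over the counts.
#'
#' @param alt1,ref1 gamete counts of the tracked/other allele, population 1
#' @param alt2,ref2 same for population 2
#' @return two-sided p-value(s)
#' @export
fisher_confirm <- function(alt1, ref1, alt2, ref2) {
  mapply(function(a1, r1, a2, r2) {
    stopifnot(a1 >= 0, r1 >= 0, a2 >= 0, r2 >= 0)
    tab <- matrix(c(a1, r1, a2, r2), nrow = 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
    stats::fisher.test(tab)$p.value
  }, alt1, ref1, alt2, ref2)
}

#' Per-level intersection counts and combined FDR estimates
#'
#' @param scan scan_result
#' @return data.frame with one row per significance level: P, l, n, d, fdr
#' @export
fdr_summary <- function(scan) {
  do.call(rbind, lapply(seq_along(scan$levels), function(i)
    combined_fdr(scan$l, scan$levels[i], scan$n_independent,
                 sum(scan$selected[, i]))))
}

#' Report of selected SNPs in the style of a selection-scan results table
#'
#' One row per SNP selected at `level`, sorted by the absolute change in
#' allele frequency (|mean focal q - reference q|, averaged over
#' comparisons) in decreasing order. Columns: snp_id, map position,
#' reference q and 2N, mean focal q with its standard error and 2N range,
#' the absolute frequency change, mean F_ST with standard error, and the
#' Fisher exact p if computed.
#'
#' @param scan scan_result
#' @param f the freq_table the scan was run on
#' @param level significance level to report (default loosest)
#' @param ref_population reference population id for the q / 2N columns
#'   (vs_original mode; ignored in group-mean mode where the reference is
#'   the per-comparison opposite-group mean)
#' @return data.frame report
#' @export
summarize_scan <- function(scan, f, level = max(scan$levels),
                           ref_population = NULL) {
  li <- match(paste0("P", level), colnames(scan$selected))
  if (is.na(li)) stop("level not in scan: ", level)
  sel <- which(scan$selected[, li])
  k <- length(scan$comparisons)
  ga <- scan$comparison_group == scan$comparison_group[1]
  mk_row <- function(j) {
    q_f <- scan$q_focal[j, ]
    q_r <- scan$q_ref[j, ]
    # group-mean mode: the frequency change is the between-group mean
    # difference; vs_original: mean survivor shift from the reference
    adq <- if (scan$mode == "vs_original") abs(mean(q_f - q_r)) else
      abs(mean(q_f[ga]) - mean(q_f[!ga]))
    two_n_f <- if (!is.null(ref_population))
      f$two_n[setdiff(f$populations, ref_population), f$snps$snp_id[j]] else
        f$two_n[, f$snps$snp_id[j]]
    data.frame(
      snp_id = scan$snps$snp_id[j], chrom = scan$snps$chrom[j],
      pos = scan$snps$pos[j],
      q_ref = if (!is.null(ref_population))
        f$q[ref_population, f$snps$snp_id[j]] else mean(q_r),
      two_n_ref = if (!is.null(ref_population))
        f$two_n[ref_population, f$snps$snp_id[j]] else NA_real_,
      mean_q = mean(q_f),
      se_q = stats::sd(q_f) / sqrt(k),
      two_n_min = min(two_n_f), two_n_max = max(two_n_f),
      abs_delta_q = adq,
      mean_fst = scan$mean_fst[j], se_fst = scan$se_fst[j],
      fisher_p = scan$fisher_p[j],
      stringsAsFactors = FALSE
    )
  }
  if (length(sel) == 0) {
    out <- mk_row(1)[0, ]
  } else {
    out <- do.call(rbind, lapply(sel, mk_row))
    out <- out[order(-out$abs_delta_q), ]
    rownames(out) <- NULL
  }
  out
}
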