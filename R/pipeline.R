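#' Run the study-1 analysis: survivor populations vs the original
#'
#' Full individual-genotype pipeline: per-call depth filtering, SNP
#' selection (genotyped in enough individuals everywhere, MAF above
#' threshold in the original), gamete-count allele frequencies polarized
#' to the original population's minor allele, the replicate-intersection
#' F_ST scan against the original, per-level combined FDR, Fisher exact
#' confirmation of hits (combined survivors vs original), a ranked report
#' of selected SNPs and a population-frequency PCA.
#'
#' @param g genotype_matrix (original + >= 2 survivor populations)
#' @param pops population_meta for the populations in `g`
#' @param fcfg filter_config
#' @param alpha_levels significance levels for the scan
#' @param verbose print l, per-level d and FDR
#' @return list: `freq`, `scan`, `fdr` (per-level table), `report`,
#'   `pca`, `snps_used`
#' @export
run_study1 <- function(g, pops, fcfg = filter_config(),
                       alpha_levels = c(0.1, 0.05, 0.01), verbose = FALSE) {
  orig <- pops$population_id[pops$role == "original"]
  surv <- pops$population_id[pops$role == "survivor"]
  if (length(orig) != 1) stop("need exactly one original population")
  if (length(surv) < 2)
    stop("intersection scan undefined with < 2 survivor populations")
  g <- filter_genotype_calls(g, fcfg)
  snps <- select_snps_individuals(g, pops, fcfg)
  g <- subset_genotypes(g, snps$snp_id)
  f <- frequencies_from_genotypes(g, c(orig, surv))
  f <- polarize_to_minor(f, orig)
  scan <- intersection_scan(f, scan_config(alpha_levels,
                                           comparison_mode = "vs_original",
                                           ref_population = orig))
  # Fisher confirmation on hits at the loosest level: combined survivors
  hits <- which(scan$selected[, 1])
  if (length(hits)) {
    flipped <- attr(f, "flipped")
    counts <- pop_allele_counts(g)
    alt_all <- counts$alt_gametes; n_all <- 2 * counts$n_geno
    tracked <- function(pop_rows, j) {
      a <- sum(alt_all[pop_rows, j]); n <- sum(n_all[pop_rows, j])
      if (flipped[j]) a <- n - a
      c(a, n - a)
    }
    o_row <- counts$pops == orig
    s_rows <- counts$pops %in% surv
    scan$fisher_p[hits] <- vapply(hits, function(j) {
      co <- tracked(o_row, j); cs <- tracked(s_rows, j)
      fisher_confirm(cs[1], cs[2], co[1], co[2])
    }, 0)
  }
  fdr <- fdr_summary(scan)
  if (verbose) {
    message(sprintf("l = %d SNPs tested in all %d comparisons",
                    scan$l, length(scan$comparisons)))
    for (i in seq_len(nrow(fdr)))
      message(sprintf("P < %-5g : d = %d, FDR = %s", fdr$P[i], fdr$d[i],
                      format(fdr$fdr[i], digits = 3)))
  }
  list(freq = f, scan = scan, fdr = fdr,
       report = summarize_scan(scan, f, ref_population = orig),
       pca = population_pca(f), snps_used = snps)
}

#' Run the study-2 analysis: pooled vs individual allele frequencies
#'
#' Filters the individual genotypes as in study 1 (call depth, genotyped
#' count, MAF among the individuals), filters the replicate pool libraries
#' to the per-library depth window, merges libraries by summing reads, and
#' reports accuracy (mean absolute deviation and r^2) of the pooled
#' frequency estimates against the individual-based ones per depth bin.
#'
#' @param g genotype_matrix of the individually genotyped population
#' @param pool pool_count_table of replicate pool libraries of the same
#'   population
#' @param fcfg filter_config (pool window defaults 10-126 per library)
#' @param bins depth bins for the report
#' @return list: `report` (accuracy_report), `f_ind`, `f_pool`, `depth`
#' @export
run_study2 <- function(g, pool, fcfg = filter_config(maf_scope = "all_samples"),
                       bins = default_depth_bins()) {
  g <- filter_genotype_calls(g, fcfg)
  pops <- population_meta(unique(g$individuals$population_id), "original",
                          n_sampled = nrow(g$dosage))
  snps_ind <- select_snps_individuals(g, pops, fcfg)
  snps_pool <- select_snps_pools(pool, fcfg, scope = "per_library")
  keep <- intersect(snps_ind$snp_id, snps_pool$snp_id)
  if (length(keep) == 0) stop("no overlapping SNPs after filtering")
  g <- subset_genotypes(g, keep)
  pool <- subset_pool_table(pool, keep)
  f_ind <- frequencies_from_genotypes(g)
  f_pool <- frequencies_from_pools(pool, "sum_replicate_libraries",
                                   n_sampled = nrow(g$dosage))
  depth <- colSums(pool_depth(pool))
  list(report = compare_pool_vs_individual(f_ind, f_pool, depth, bins),
       f_ind = f_ind, f_pool = f_pool, depth = depth)
}

# column subset of a pool_count_table
subset_pool_table <- function(p, snp_ids) {
  j <- match(snp_ids, p$snps$snp_id)
  pool_count_table(p$pools, p$snps[j, , drop = FALSE],
                   p$counts_ref[, j, drop = FALSE],
                   p$counts_alt[, j, drop = FALSE])
}

#' Run the study-3 analysis: differential selection between treatments
#'
#' Pool-sample pipeline: SNP filtering (depth window and MAF in every
#' sample, chromosomal SNPs only), per-library frequencies, averaging of
#' replicate pools per plot, polarization to the first plot's minor
#' allele, the intersection scan of each plot against the opposite
#' stand-type group's mean (8 comparisons, n = 4 independent), per-level
#' combined FDR, and a two-way ANOVA (stand x density) over a candidate
#' SNP list.
#'
#' @param pool pool_count_table for the 8 treatment populations (replicate
#'   pools share a pool_id)
#' @param design data.frame `population_id`, `stand`, `density` (one row
#'   per plot population)
#' @param fcfg filter_config; default window 100-499, MAF > 0.05 in all
#'   samples
#' @param alpha_levels significance levels
#' @param candidates SNP ids for the ANOVA stage (e.g. an external outlier
#'   list); NULL skips the stage with a message; "scan_hits" uses the
#'   intersection hits at the loosest level
#' @param n_gametes nominal gamete count per pool (2 x individuals pooled)
#' @param chromosomal_only restrict to chromosome-anchored SNPs
#' @param verbose print l, d, FDR lines
#' @return list: `freq` (per plot), `scan`, `fdr`, `report`, `anova`,
#'   `classes`, `pca`
#' @export
run_study3 <- function(pool, design,
                       fcfg = filter_config(maf_scope = "all_samples",
                                            pool_depth_min = 100L,
                                            pool_depth_max = 499L),
                       alpha_levels = c(0.1, 0.05, 0.01),
                       candidates = "scan_hits", n_gametes = 200,
                       chromosomal_only = TRUE, verbose = FALSE) {
  if (!all(pool$pools$population_id %in% design$population_id))
    stop("missing treatment metadata for some pools")
  snps <- select_snps_pools(pool, fcfg, scope = "all_samples",
                            chromosomal_only = chromosomal_only)
  if (nrow(snps) == 0) stop("no SNPs pass the pool filters")
  pool <- subset_pool_table(pool, snps$snp_id)
  f_pools <- frequencies_from_pools(pool, "per_pool",
                                    n_sampled = n_gametes / 2)
  plot_of <- stats::setNames(
    pool$pools$pool_id[match(f_pools$populations, pool$pools$library_id)],
    f_pools$populations)
  f <- average_replicate_pools(f_pools, plot_of)
  f <- polarize_to_minor(f, f$populations[1])
  groups <- stats::setNames(
    design$stand[match(f$populations, design$population_id)], f$populations)
  scan <- intersection_scan(
    f, scan_config(alpha_levels, comparison_mode = "vs_opposite_group_mean",
                   groups = groups))
  fdr <- fdr_summary(scan)
  if (verbose) {
    message(sprintf("l = %d SNPs tested in all %d comparisons",
                    scan$l, length(scan$comparisons)))
    for (i in seq_len(nrow(fdr)))
      message(sprintf("P < %-5g : d = %d, FDR = %s", fdr$P[i], fdr$d[i],
                      format(fdr$fdr[i], digits = 3)))
  }
  if (identical(candidates, "scan_hits"))
    candidates <- scan$snps$snp_id[scan$selected[, 1]]
  anova_tab <- NULL; classes <- NULL
  if (is.null(candidates) || length(candidates) == 0) {
    message("no candidate SNPs; ANOVA stage skipped")
  } else {
    anova_tab <- anova_scan(f, design, candidates)
    classes <- classify_candidates(anova_tab)
  }
  list(freq = f, scan = scan, fdr = fdr,
       report = summarize_scan(scan, f),
       anova = anova_tab, classes = classes,
       pca = population_pca(f))
}
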