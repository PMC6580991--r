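#' Quality-filter configuration
#'
#' Holds every genotype- and SNP-level inclusion rule of the pipeline.
#' Defaults are the thresholds used for individual GBS genotypes: a call
#' needs at least 10 reads in total and, for heterozygotes, at least 2
#' reads per allele; a SNP needs an established genotype in at least 25
#' individuals in every population and minor allele frequency above 0.05
#' in the reference population. Pool depth windows are inclusive on both
#' ends (10-126 reads per replicate DNA-pool library; 100-499 reads for
#' leaf-pool samples).
#'
#' @param min_total_reads minimum total read depth per genotype call.
#' @param min_reads_per_het_allele minimum depth of each allele for a
#'   heterozygous call.
#' @param min_genotyped_per_pop minimum genotyped individuals per
#'   population for a SNP to be kept.
#' @param maf_threshold strict lower bound on minor allele frequency.
#' @param maf_scope "original_only" or "all_samples".
#' @param pool_depth_min,pool_depth_max inclusive read-depth window for
#'   pooled samples.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(min_total_reads = 10L,
                          min_reads_per_het_allele = 2L,
                          min_genotyped_per_pop = 25L,
                          maf_threshold = 0.05,
                          maf_scope = c("original_only", "all_samples"),
                          pool_depth_min = 10L,
                          pool_depth_max = 126L) {
  maf_scope <- match.arg(maf_scope)
  stopifnot(min_total_reads >= 0, min_reads_per_het_allele >= 0,
            min_genotyped_per_pop >= 0, maf_threshold >= 0,
            pool_depth_min < pool_depth_max)
  structure(list(min_total_reads = min_total_reads,
                 min_reads_per_het_allele = min_reads_per_het_allele,
                 min_genotyped_per_pop = min_genotyped_per_pop,
                 maf_threshold = maf_threshold,
                 maf_scope = maf_scope,
                 pool_depth_min = pool_depth_min,
                 pool_depth_max = pool_depth_max),
            class = "filter_config")
}

#' Apply per-call depth filters to genotype calls
#'
#' Sets a call to missing when its total read depth is below
#' `min_total_reads`, or, for heterozygous calls only, when either allele
#' was seen fewer than `min_reads_per_het_allele` times. Homozygous calls
#' are unaffected by the per-allele rule. Pure transformation: depths are
#' kept, only dosage is masked.
#'
#' @param g genotype_matrix
#' @param cfg filter_config
#' @return genotype_matrix with failing calls set missing
#' @export
filter_genotype_calls <- function(g, cfg = filter_config()) {
  total <- g$depth_ref + g$depth_alt
  drop <- total < cfg$min_total_reads
  het <- !is.na(g$dosage) & g$dosage == 1L
  drop <- drop | (het & (g$depth_ref < cfg$min_reads_per_het_allele |
                           g$depth_alt < cfg$min_reads_per_het_allele))
  g$dosage[drop] <- NA_integer_
  g
}

# per-population counts of genotyped individuals and alt gametes
pop_allele_counts <- function(g) {
  pops <- unique(g$individuals$population_id)
  n_geno <- matrix(0L, length(pops), ncol(g$dosage),
                   dimnames = list(pops, colnames(g$dosage)))
  alt <- n_geno
  for (p in pops) {
    rows <- g$individuals$population_id == p
    d <- g$dosage[rows, , drop = FALSE]
    n_geno[p, ] <- colSums(!is.na(d))
    alt[p, ] <- colSums(d, na.rm = TRUE)
  }
  list(pops = pops, n_geno = n_geno, alt_gametes = alt)
}

#' Select SNPs from individual genotype data
#'
#' Keeps SNPs with an established genotype in at least
#' `min_genotyped_per_pop` individuals in every population, and minor
#' allele frequency strictly above `maf_threshold` in the population(s)
#' named by `maf_scope` ("original_only": the population(s) with role
#' "original" in `pops`; "all_samples": allele counts pooled over all
#' individuals). MAF is computed by gamete counting over retained calls.
#'
#' @param g call-filtered genotype_matrix
#' @param pops population_meta
#' @param cfg filter_config
#' @return SNP metadata data.frame of the retained SNPs
#' @export
select_snps_individuals <- function(g, pops, cfg = filter_config()) {
  counts <- pop_allele_counts(g)
  if (any(table(factor(g$individuals$population_id,
                       levels = counts$pops)) == 0))
    stop("population with zero individuals")
  enough <- colSums(counts$n_geno >= cfg$min_genotyped_per_pop) ==
    length(counts$pops)
  if (cfg$maf_scope == "original_only") {
    ref_pops <- pops$population_id[pops$role == "original"]
    if (length(ref_pops) == 0) stop("no population with role 'original'")
    rows <- counts$pops %in% ref_pops
  } else {
    rows <- rep(TRUE, length(counts$pops))
  }
  alt <- colSums(counts$alt_gametes[rows, , drop = FALSE])
  two_n <- 2 * colSums(counts$n_geno[rows, , drop = FALSE])
  q <- ifelse(two_n > 0, alt / two_n, NA_real_)
  maf <- pmin(q, 1 - q)
  keep <- enough & !is.na(maf) & maf > cfg$maf_threshold
  g$snps[keep, , drop = FALSE]
}

#' Select SNPs from pooled read counts
#'
#' Depth windows are inclusive on both ends. Scope `per_library` requires
#' `pool_depth_min <= depth <= pool_depth_max` within every replicate
#' library; `all_samples` additionally requires minor allele frequency
#' above `maf_threshold` in every library; `after_merge` applies the depth
#' window to counts summed over the replicate libraries of each pool.
#'
#' @param p pool_count_table
#' @param cfg filter_config
#' @param scope "per_library", "after_merge" or "all_samples"
#' @param chromosomal_only if TRUE, additionally drop SNPs without a
#'   chromosome assignment (tags mapping to unanchored scaffolds)
#' @return SNP metadata data.frame of the retained SNPs
#' @export
select_snps_pools <- function(p, cfg = filter_config(),
                              scope = c("per_library", "after_merge",
                                        "all_samples"),
                              chromosomal_only = FALSE) {
  scope <- match.arg(scope)
  depth <- pool_depth(p)
  in_window <- function(d) d >= cfg$pool_depth_min & d <= cfg$pool_depth_max
  if (scope == "after_merge") {
    by_pool <- rowsum(depth, p$pools$pool_id)
    keep <- colSums(in_window(by_pool)) == nrow(by_pool)
  } else {
    keep <- colSums(in_window(depth)) == nrow(depth)
    if (scope == "all_samples") {
      q <- p$counts_alt / ifelse(depth > 0, depth, NA)
      maf <- pmin(q, 1 - q)
      keep <- keep & colSums(!is.na(maf) & maf > cfg$maf_threshold) ==
        nrow(depth)
    }
  }
  if (chromosomal_only) keep <- keep & !is.na(p$snps$chrom)
  p$snps[keep, , drop = FALSE]
}
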