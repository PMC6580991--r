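#' Allele frequencies from individual genotypes
#'
#' Gamete counting: per population and SNP, `q` is the alt-allele gamete
#' count over `2N`, where `2N` is twice the number of genotyped (non-missing)
#' individuals. Populations with no genotyped individual at a SNP get
#' `q = NA`, `2N = 0`.
#'
#' @param g filtered genotype_matrix
#' @param populations optional character vector restricting/ordering the
#'   populations (must all be present in `g`)
#' @return freq_table tracking the alt allele
#' @export
frequencies_from_genotypes <- function(g, populations = NULL) {
  counts <- pop_allele_counts(g)
  pops <- counts$pops
  if (!is.null(populations)) {
    if (!all(populations %in% pops))
      stop("population absent from genotype matrix: ",
           paste(setdiff(populations, pops), collapse = ", "))
    pops <- populations
  }
  two_n <- 2 * counts$n_geno[pops, , drop = FALSE]
  q <- ifelse(two_n > 0, counts$alt_gametes[pops, , drop = FALSE] / two_n,
              NA_real_)
  freq_table(g$snps, pops, q, two_n)
}

#' Allele frequencies from pooled read counts
#'
#' With `merge = "sum_replicate_libraries"` the counts of all replicate
#' libraries of a pool are summed before taking the ratio
#' `q = alt / (ref + alt)` (ratio of sums, not mean of ratios). With
#' `merge = "per_pool"` each library is kept as its own sample. Zero depth
#' after merging gives `q = NA`. The gamete count `2N` is nominal:
#' `2 * n_sampled` individuals contributing to the pool.
#'
#' @param p filtered pool_count_table
#' @param merge "sum_replicate_libraries" or "per_pool"
#' @param n_sampled individuals per pool: single number or named vector by
#'   pool_id (default 100 leaves/individuals per pool)
#' @return freq_table tracking the alt allele; population ids are pool ids
#'   (merged) or library ids (per_pool)
#' @export
frequencies_from_pools <- function(p,
                                   merge = c("sum_replicate_libraries",
                                             "per_pool"),
                                   n_sampled = 100) {
  merge <- match.arg(merge)
  if (merge == "sum_replicate_libraries") {
    ref <- rowsum(p$counts_ref, p$pools$pool_id)
    alt <- rowsum(p$counts_alt, p$pools$pool_id)
    ids <- rownames(ref)
  } else {
    ref <- p$counts_ref; alt <- p$counts_alt
    ids <- p$pools$library_id
  }
  depth <- ref + alt
  q <- ifelse(depth > 0, alt / depth, NA_real_)
  n_per <- if (length(n_sampled) == 1) rep(n_sampled, length(ids)) else {
    key <- if (merge == "sum_replicate_libraries") ids else
      p$pools$pool_id
    unname(n_sampled[key])
  }
  two_n <- matrix(2 * n_per, length(ids), ncol(q))
  two_n[is.na(q)] <- 0
  freq_table(p$snps, ids, q, two_n)
}

#' Average replicate pool frequencies per plot
#'
#' Unweighted mean of `q` over the replicate pools mapped to each plot;
#' `NA` replicates are excluded from the mean (all-NA gives NA). The
#' nominal gamete count of a plot is the mean of its replicates'.
#'
#' @param f freq_table whose populations are pools
#' @param groups named character vector mapping every pool id to a plot id
#' @return freq_table with plots as populations
#' @export
average_replicate_pools <- function(f, groups) {
  if (!all(f$populations %in% names(groups)))
    stop("every pool must be mapped to a plot")
  plot_of <- groups[f$populations]
  plots <- unique(unname(plot_of))
  q <- matrix(NA_real_, length(plots), ncol(f$q),
              dimnames = list(plots, colnames(f$q)))
  two_n <- q
  for (pl in plots) {
    rows <- plot_of == pl
    qq <- f$q[rows, , drop = FALSE]
    n_ok <- colSums(!is.na(qq))
    q[pl, ] <- ifelse(n_ok > 0, colMeans(qq, na.rm = TRUE), NA_real_)
    two_n[pl, ] <- ifelse(n_ok > 0,
                          colSums(f$two_n[rows, , drop = FALSE] *
                                    !is.na(qq)) / n_ok, 0)
  }
  freq_table(f$snps, plots, q, two_n)
}

#' Polarize a frequency table to the minor allele of a reference population
#'
#' Fixes the tracked allele per SNP as the minor allele of
#' `reference_population` (or of the first population if NULL), flipping
#' `q := 1 - q` in every population where needed. Keeps cross-population
#' frequency differences comparable and makes the reference column a MAF.
#'
#' @param f freq_table
#' @param reference_population population id; default first listed
#' @return freq_table with attribute "flipped" (logical per SNP)
#' @export
polarize_to_minor <- function(f, reference_population = NULL) {
  ref <- if (is.null(reference_population)) f$populations[1] else
    reference_population
  if (!ref %in% f$populations) stop("unknown reference population: ", ref)
  flip <- !is.na(f$q[ref, ]) & f$q[ref, ] > 0.5
  f$q[, flip] <- 1 - f$q[, flip]
  attr(f, "flipped") <- flip
  f
}

#' Pooled vs individual allele-frequency accuracy by depth bin
#'
#' For each read-depth bin, reports the number of SNPs, the mean absolute
#' deviation |q_pool - q_ind| and the squared Pearson correlation of the
#' two frequency vectors. SNPs are assigned to bins by the merged pool
#' depth. Bins with fewer than 2 SNPs get `r_squared = NA`.
#'
#' @param f_ind freq_table from individuals (one population row used)
#' @param f_pool freq_table from pools (one population row used)
#' @param depth named numeric vector of merged pool read depth per SNP
#' @param bins list of `c(lo, hi)` inclusive depth intervals; default the
#'   standard report bins 10-49 ... >599
#' @param ind_population,pool_population row to use from each table
#'   (defaults to the first)
#' @return data.frame with columns bin_lo, bin_hi, n_snps,
#'   mean_abs_deviation, r_squared
#' @export
compare_pool_vs_individual <- function(f_ind, f_pool, depth,
                                       bins = default_depth_bins(),
                                       ind_population = f_ind$populations[1],
                                       pool_population = f_pool$populations[1]) {
  common <- intersect(f_ind$snps$snp_id, f_pool$snps$snp_id)
  if (length(common) == 0) stop("no overlapping SNPs")
  qi <- f_ind$q[ind_population, common]
  qp <- f_pool$q[pool_population, common]
  d <- depth[common]
  ok <- !is.na(qi) & !is.na(qp) & !is.na(d)
  qi <- qi[ok]; qp <- qp[ok]; d <- d[ok]
  out <- do.call(rbind, lapply(bins, function(b) {
    sel <- d >= b[1] & d <= b[2]
    n <- sum(sel)
    data.frame(
      bin_lo = b[1], bin_hi = b[2], n_snps = n,
      mean_abs_deviation = if (n > 0) mean(abs(qp[sel] - qi[sel])) else NA_real_,
      r_squared = if (n >= 2 && stats::sd(qi[sel]) > 0 && stats::sd(qp[sel]) > 0)
        stats::cor(qi[sel], qp[sel])^2 else NA_real_
    )
  }))
  class(out) <- c("accuracy_report", "data.frame")
  out
}

#' Default pool-depth bins for the accuracy report
#' @return list of inclusive `c(lo, hi)` intervals
#' @export
default_depth_bins <- function() {
  list(c(10, 49), c(50, 99), c(100, 149), c(150, 199), c(200, 299),
       c(300, 399), c(400, 499), c(500, 599), c(600, Inf))
}
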