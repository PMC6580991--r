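#' Construct a genotype matrix
#'
#' The central container for individual-level GBS data: biallelic SNP
#' metadata, individual/population labels, alt-allele dosage calls and
#' per-allele read depths. Matrices are oriented individuals x SNPs.
#'
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos`, `ref`,
#'   `alt`. `chrom`/`pos` may be `NA` for unanchored tags; positions are
#'   1-based.
#' @param individuals data.frame with columns `individual_id`,
#'   `population_id`.
#' @param dosage integer matrix (individuals x SNPs) of alt-allele counts
#'   in {0, 1, 2}; `NA` = missing call.
#' @param depth_ref,depth_alt non-negative integer matrices of per-allele
#'   read depths, same shape as `dosage`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(snps, individuals, dosage, depth_ref, depth_alt) {
  snps <- as.data.frame(snps)
  individuals <- as.data.frame(individuals)
  stopifnot(
    all(c("snp_id", "chrom", "pos", "ref", "alt") %in% names(snps)),
    all(c("individual_id", "population_id") %in% names(individuals)),
    !anyDuplicated(snps$snp_id),
    nrow(dosage) == nrow(individuals), ncol(dosage) == nrow(snps),
    identical(dim(dosage), dim(depth_ref)),
    identical(dim(dosage), dim(depth_alt))
  )
  if (any(depth_ref < 0, na.rm = TRUE) || any(depth_alt < 0, na.rm = TRUE))
    stop("read depths must be non-negative")
  if (!all(dosage %in% c(0L, 1L, 2L, NA)))
    stop("dosage must be 0, 1, 2 or NA")
  bad_pos <- !is.na(snps$chrom) & !is.na(snps$pos) & snps$pos < 1
  if (any(bad_pos)) stop("positions must be >= 1 when a chromosome is set")
  dimnames(dosage) <- dimnames(depth_ref) <- dimnames(depth_alt) <-
    list(individuals$individual_id, snps$snp_id)
  structure(
    list(snps = snps, individuals = individuals, dosage = dosage,
         depth_ref = depth_ref, depth_alt = depth_alt),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d individuals x %d SNPs, %d populations; %.1f%% missing calls\n",
              nrow(x$dosage), ncol(x$dosage),
              length(unique(x$individuals$population_id)),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by SNP id and/or individual index
#'
#' @param g genotype_matrix
#' @param snp_ids character vector of SNP ids to keep (in given order)
#' @param individuals optional logical/integer index over individuals
#' @return genotype_matrix
#' @export
subset_genotypes <- function(g, snp_ids = g$snps$snp_id,
                             individuals = seq_len(nrow(g$dosage))) {
  j <- match(snp_ids, g$snps$snp_id)
  if (anyNA(j)) stop("unknown snp_id in subset")
  genotype_matrix(
    snps = g$snps[j, , drop = FALSE],
    individuals = g$individuals[individuals, , drop = FALSE],
    dosage = g$dosage[individuals, j, drop = FALSE],
    depth_ref = g$depth_ref[individuals, j, drop = FALSE],
    depth_alt = g$depth_alt[individuals, j, drop = FALSE]
  )
}

#' Construct a pool count table
#'
#' Read counts from sequencing of pooled samples: one row per pool library,
#' one column per SNP. Replicate libraries of the same physical pool share a
#' `pool_id` and are distinguished by `library_id`.
#'
#' @param pools data.frame with columns `pool_id`, `population_id`,
#'   `replicate_index`, `library_id`.
#' @param snps SNP metadata data.frame as for [genotype_matrix()].
#' @param counts_ref,counts_alt non-negative integer matrices
#'   (pools x SNPs).
#' @return An object of class `pool_count_table`.
#' @export
pool_count_table <- function(pools, snps, counts_ref, counts_alt) {
  pools <- as.data.frame(pools)
  snps <- as.data.frame(snps)
  stopifnot(
    all(c("pool_id", "population_id", "replicate_index", "library_id") %in%
          names(pools)),
    nrow(counts_ref) == nrow(pools), ncol(counts_ref) == nrow(snps),
    identical(dim(counts_ref), dim(counts_alt))
  )
  if (any(counts_ref < 0, na.rm = TRUE) || any(counts_alt < 0, na.rm = TRUE))
    stop("read counts must be non-negative")
  dimnames(counts_ref) <- dimnames(counts_alt) <-
    list(pools$library_id, snps$snp_id)
  structure(
    list(pools = pools, snps = snps, counts_ref = counts_ref,
         counts_alt = counts_alt),
    class = "pool_count_table"
  )
}

#' @export
print.pool_count_table <- function(x, ...) {
  cat(sprintf("<pool_count_table> %d libraries (%d pools) x %d SNPs\n",
              nrow(x$pools), length(unique(x$pools$pool_id)), nrow(x$snps)))
  invisible(x)
}

#' Pool read depth (ref + alt) matrix
#' @param p pool_count_table
#' @return integer matrix libraries x SNPs
#' @export
pool_depth <- function(p) p$counts_ref + p$counts_alt

#' Construct an allele-frequency table
#'
#' Per-population frequency `q` of one fixed tracked allele per SNP, plus
#' the genotyped-gamete count `2N` behind each estimate (twice the number
#' of genotyped individuals, or the nominal gamete count of a pool).
#'
#' @param snps SNP metadata data.frame.
#' @param populations character vector of population ids (rows of `q`).
#' @param q numeric matrix (populations x SNPs) of frequencies in [0, 1];
#'   `NA` where no data.
#' @param two_n numeric matrix of gamete counts, same shape; even, >= 0.
#' @return An object of class `freq_table`.
#' @export
freq_table <- function(snps, populations, q, two_n) {
  snps <- as.data.frame(snps)
  q <- as.matrix(q); two_n <- as.matrix(two_n)
  stopifnot(
    nrow(q) == length(populations), ncol(q) == nrow(snps),
    identical(dim(q), dim(two_n))
  )
  if (any(q < -1e-12 | q > 1 + 1e-12, na.rm = TRUE))
    stop("frequencies must lie in [0, 1]")
  if (any(two_n < 0, na.rm = TRUE)) stop("gamete counts must be >= 0")
  dimnames(q) <- dimnames(two_n) <- list(populations, snps$snp_id)
  structure(
    list(snps = snps, populations = populations, q = q, two_n = two_n),
    class = "freq_table"
  )
}

#' @export
print.freq_table <- function(x, ...) {
  cat(sprintf("<freq_table> %d populations x %d SNPs\n",
              length(x$populations), nrow(x$snps)))
  invisible(x)
}

#' Population metadata table
#'
#' @param population_id character ids.
#' @param role "original" or "survivor".
#' @param stand_type "pure", "mixed" or NA.
#' @param seeding_density "high", "low" or NA.
#' @param harvest_regime "3H", "5H" or NA.
#' @param replicate_plot integer plot number (NA for the original).
#' @param n_sampled sampled individuals per population (> 0).
#' @return data.frame of class `population_meta`.
#' @export
population_meta <- function(population_id, role, stand_type = NA,
                            seeding_density = NA, harvest_regime = NA,
                            replicate_plot = NA, n_sampled) {
  stopifnot(all(role %in% c("original", "survivor")), all(n_sampled > 0))
  out <- data.frame(
    population_id = population_id, role = role,
    stand_type = stand_type, seeding_density = seeding_density,
    harvest_regime = harvest_regime, replicate_plot = replicate_plot,
    n_sampled = n_sampled, stringsAsFactors = FALSE
  )
  orig <- out$role == "original"
  # the original (sown) population never has field-treatment levels
  out$stand_type[orig] <- NA
  out$seeding_density[orig] <- NA
  out$harvest_regime[orig] <- NA
  class(out) <- c("population_meta", "data.frame")
  out
}

# minimal SNP metadata constructor used by readers and the simulator
snp_records <- function(snp_id, chrom = NA_character_, pos = NA_integer_,
                        ref = "A", alt = "C") {
  n <- length(snp_id)
  data.frame(snp_id = as.character(snp_id),
             chrom = rep_len(as.character(chrom), n),
             pos = rep_len(as.integer(pos), n),
             ref = rep_len(ref, n), alt = rep_len(alt, n),
             stringsAsFactors = FALSE)
}
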