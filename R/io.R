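#' Read a genotype matrix from VCF or the package TSV dialect
#'
#' The TSV dialect has one row per SNP: columns `snp_id chrom pos ref alt`
#' followed by one column per individual holding `dosage:refDepth:altDepth`
#' with missing dosage encoded `.` (e.g. `1:4:6`, `.:3:0`). Individual
#' column headers are `individual_id@population_id`. VCF input must carry
#' per-allele depths in an AD FORMAT field; multiallelic records are
#' skipped with a warning.
#'
#' @param path file path.
#' @param dialect "tsv" or "vcf".
#' @param population_map for VCF input, a named character vector mapping
#'   sample id to population id (defaults to one population "pop1").
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, dialect = c("tsv", "vcf"),
                           population_map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "tsv") read_genotypes_tsv(path) else
    read_genotypes_vcf(path, population_map)
}

read_genotypes_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           comment.char = "")
  fixed <- c("snp_id", "chrom", "pos", "ref", "alt")
  if (!identical(names(tab)[1:5], fixed))
    stop("malformed header: expected columns ", paste(fixed, collapse = " "),
         " at line 1")
  ind_cols <- names(tab)[-(1:5)]
  ids <- sub("@.*$", "", ind_cols)
  pops <- sub("^[^@]*@", "", ind_cols)
  snps <- snp_records(tab$snp_id,
                      chrom = ifelse(tab$chrom %in% c("", "."), NA, tab$chrom),
                      pos = suppressWarnings(as.integer(
                        ifelse(tab$pos %in% c("", "."), NA, tab$pos))),
                      ref = tab$ref, alt = tab$alt)
  n_snp <- nrow(tab); n_ind <- length(ind_cols)
  dosage <- matrix(NA_integer_, n_ind, n_snp)
  dref <- matrix(0L, n_ind, n_snp)
  dalt <- matrix(0L, n_ind, n_snp)
  for (i in seq_along(ind_cols)) {
    parts <- strsplit(tab[[ind_cols[i]]], ":", fixed = TRUE)
    bad <- lengths(parts) != 3
    if (any(bad))
      stop("malformed genotype field at line ", which(bad)[1] + 1L,
           " (expected dosage:refDepth:altDepth)")
    m <- matrix(unlist(parts), ncol = 3, byrow = TRUE)
    dosage[i, ] <- suppressWarnings(as.integer(ifelse(m[, 1] == ".", NA, m[, 1])))
    dref[i, ] <- as.integer(m[, 2])
    dalt[i, ] <- as.integer(m[, 3])
  }
  genotype_matrix(snps, data.frame(individual_id = ids, population_id = pops,
                                   stringsAsFactors = FALSE),
                  dosage, dref, dalt)
}

read_genotypes_vcf <- function(path, population_map = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multiallelic record(s) skipped")
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  snps <- snp_records(
    snp_id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                    paste0(fix[, "CHROM"], "_", fix[, "POS"]), fix[, "ID"]),
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"]
  )
  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(ad)) stop("VCF lacks an AD (per-allele depth) FORMAT field")
  # genotype calls are optional: depth-only VCFs yield all-missing dosages
  gt <- tryCatch(vcfR::extract.gt(vcf, element = "GT"),
                 error = function(e) NULL)
  if (is.null(gt)) {
    gt <- ad
    gt[] <- NA_character_
  }
  samples <- colnames(gt)
  parse_ad <- function(x, k) {
    v <- suppressWarnings(as.integer(vapply(
      strsplit(ifelse(is.na(x), "0,0", x), ",", fixed = TRUE),
      function(p) if (length(p) >= k) p[k] else "0", "")))
    v[is.na(v)] <- 0L
    v
  }
  n_snp <- nrow(snps); n_ind <- length(samples)
  dref <- matrix(0L, n_ind, n_snp); dalt <- matrix(0L, n_ind, n_snp)
  dosage <- matrix(NA_integer_, n_ind, n_snp)
  for (i in seq_len(n_ind)) {
    dref[i, ] <- parse_ad(ad[, i], 1L)
    dalt[i, ] <- parse_ad(ad[, i], 2L)
    g <- gt[, i]
    g <- gsub("|", "/", g, fixed = TRUE)
    dosage[i, ] <- ifelse(is.na(g) | g %in% c("./.", "."), NA_integer_,
                          ifelse(g == "0/0", 0L, ifelse(g == "1/1", 2L,
                          ifelse(g %in% c("0/1", "1/0"), 1L, NA_integer_))))
  }
  if (is.null(population_map))
    population_map <- stats::setNames(rep("pop1", n_ind), samples)
  genotype_matrix(snps,
                  data.frame(individual_id = samples,
                             population_id = unname(population_map[samples]),
                             stringsAsFactors = FALSE),
                  dosage, dref, dalt)
}

#' Write a genotype matrix in the package TSV dialect
#'
#' @param g genotype_matrix
#' @param path output file path
#' @export
write_genotypes <- function(g, path) {
  cells <- matrix(sprintf("%s:%d:%d",
                          ifelse(is.na(g$dosage), ".", g$dosage),
                          g$depth_ref, g$depth_alt),
                  nrow = nrow(g$dosage))
  header <- c("snp_id", "chrom", "pos", "ref", "alt",
              paste0(g$individuals$individual_id, "@",
                     g$individuals$population_id))
  body <- cbind(g$snps$snp_id,
                ifelse(is.na(g$snps$chrom), ".", g$snps$chrom),
                ifelse(is.na(g$snps$pos), ".", g$snps$pos),
                g$snps$ref, g$snps$alt, t(cells))
  utils::write.table(rbind(header, body), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read pooled read counts from a long-format TSV
#'
#' Expected columns: `pool_id`, `library_id`, `replicate_index`,
#' `population_id`, `snp_id`, `ref_count`, `alt_count` (optionally `chrom`,
#' `pos`). Duplicate (library, SNP) rows are summed with a message; an
#' empty file yields an empty table.
#'
#' @param path file path.
#' @return A [pool_count_table()].
#' @export
read_pool_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "")
  need <- c("pool_id", "library_id", "replicate_index", "population_id",
            "snp_id", "ref_count", "alt_count")
  if (nrow(tab) == 0) {
    return(pool_count_table(
      pools = data.frame(pool_id = character(), population_id = character(),
                         replicate_index = integer(), library_id = character()),
      snps = snp_records(character()),
      counts_ref = matrix(0L, 0, 0), counts_alt = matrix(0L, 0, 0)))
  }
  if (!all(need %in% names(tab)))
    stop("pool count file must have columns: ", paste(need, collapse = ", "))
  if (any(tab$ref_count < 0) || any(tab$alt_count < 0))
    stop("negative read counts in ", path)
  key <- paste(tab$library_id, tab$snp_id, sep = "\r")
  if (anyDuplicated(key)) {
    message(sum(duplicated(key)), " duplicate (library, snp) rows summed")
    tab$ref_count <- stats::ave(tab$ref_count, key, FUN = sum)
    tab$alt_count <- stats::ave(tab$alt_count, key, FUN = sum)
    tab <- tab[!duplicated(key), ]
  }
  libs <- unique(tab[c("pool_id", "population_id", "replicate_index",
                       "library_id")])
  snp_ids <- unique(tab$snp_id)
  chrom <- rep(NA_character_, length(snp_ids))
  pos <- rep(NA_integer_, length(snp_ids))
  if (all(c("chrom", "pos") %in% names(tab))) {
    first <- tab[!duplicated(tab$snp_id), ]
    chrom <- ifelse(first$chrom %in% c("", "."), NA, first$chrom)
    pos <- suppressWarnings(as.integer(first$pos))
  }
  cr <- matrix(0L, nrow(libs), length(snp_ids),
               dimnames = list(libs$library_id, snp_ids))
  ca <- cr
  i <- match(tab$library_id, libs$library_id)
  j <- match(tab$snp_id, snp_ids)
  cr[cbind(i, j)] <- as.integer(tab$ref_count)
  ca[cbind(i, j)] <- as.integer(tab$alt_count)
  pool_count_table(libs, snp_records(snp_ids, chrom, pos), cr, ca)
}

#' Write pooled read counts in the long TSV format read by
#' [read_pool_counts()]
#' @param p pool_count_table
#' @param path output file path
#' @export
write_pool_counts <- function(p, path) {
  n_lib <- nrow(p$pools); n_snp <- nrow(p$snps)
  out <- data.frame(
    pool_id = rep(p$pools$pool_id, each = n_snp),
    library_id = rep(p$pools$library_id, each = n_snp),
    replicate_index = rep(p$pools$replicate_index, each = n_snp),
    population_id = rep(p$pools$population_id, each = n_snp),
    snp_id = rep(p$snps$snp_id, times = n_lib),
    chrom = rep(ifelse(is.na(p$snps$chrom), ".", p$snps$chrom), times = n_lib),
    pos = rep(ifelse(is.na(p$snps$pos), ".", p$snps$pos), times = n_lib),
    ref_count = as.integer(t(p$counts_ref)),
    alt_count = as.integer(t(p$counts_alt))
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a frequency table as TSV (long format)
#' @param f freq_table
#' @param path output path
#' @export
write_freq_table <- function(f, path) {
  out <- data.frame(
    population_id = rep(f$populations, each = nrow(f$snps)),
    snp_id = rep(f$snps$snp_id, times = length(f$populations)),
    q = as.numeric(t(f$q)),
    two_n = as.numeric(t(f$two_n))
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

#' Write scan results as a flat TSV
#'
#' One row per SNP with per-comparison F_ST / chi-square / p columns,
#' per-level selection flags and the summary statistics. NA p-values
#' (untested SNPs) serialize as "NA". Round-trips through
#' [read_scan_results()].
#'
#' @param result scan_result from [intersection_scan()]
#' @param path output file path
#' @export
write_scan_results <- function(result, path) {
  df <- as.data.frame(result)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA, format(x, digits = 17, scientific = TRUE,
                                trim = TRUE))
  })
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}

#' Read scan results written by [write_scan_results()]
#' @param path file path
#' @return data.frame (flat form of a scan result)
#' @export
read_scan_results <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    na.strings = "NA", check.names = FALSE)
}
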