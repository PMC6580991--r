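#' PCA of population allele frequencies
#'
#' Mean-centers the populations x SNPs frequency matrix SNP-wise (no
#' unit-variance scaling) and decomposes it by singular values. SNPs with
#' any missing frequency are dropped.
#'
#' @param f freq_table
#' @param scale. optionally scale SNP columns to unit variance
#' @return list of class `pca_result`: `scores` (entities x components),
#'   `variance_fraction`, `loadings`, `sdev`
#' @export
population_pca <- function(f, scale. = FALSE) {
  if (length(f$populations) < 2) stop("need at least 2 populations")
  x <- f$q[, colSums(is.na(f$q)) == 0, drop = FALSE]
  pca_from_matrix(x, scale.)
}

#' PCA of individual genotypes
#'
#' Individuals x SNPs dosage matrix; missing calls are imputed with the
#' SNP mean, SNPs with no calls at all are dropped, columns are centered
#' (no scaling by default).
#'
#' @param g genotype_matrix
#' @param scale. optionally scale to unit variance (zero-variance SNPs
#'   dropped first)
#' @return `pca_result` with one score row per individual
#' @export
genotype_pca <- function(g, scale. = FALSE) {
  x <- g$dosage
  keep <- colSums(!is.na(x)) > 0
  x <- x[, keep, drop = FALSE]
  mu <- colMeans(x, na.rm = TRUE)
  idx <- which(is.na(x))
  if (length(idx)) x[idx] <- mu[((idx - 1) %/% nrow(x)) + 1]
  pca_from_matrix(x, scale.)
}

pca_from_matrix <- function(x, scale. = FALSE) {
  if (scale.) {
    v <- apply(x, 2, stats::sd)
    x <- x[, v > 0, drop = FALSE]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = scale.)
  total_var <- sum(apply(scale(x, center = TRUE, scale = scale.), 2,
                         stats::var))
  vf <- if (total_var > 0) pc$sdev^2 / total_var else rep(0, length(pc$sdev))
  structure(list(scores = pc$x, variance_fraction = vf,
                 loadings = pc$rotation, sdev = pc$sdev,
                 center = pc$center),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d entities, %d components; PC1-3 variance: %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(sprintf("%.1f%%",
                            100 * utils::head(x$variance_fraction, 3)),
                    collapse = ", ")))
  invisible(x)
}

# exact 1-dimensional 2-means: minimize within-cluster SS over all sorted
# split points; deterministic, no random restarts
split_1d_2means <- function(x) {
  n <- length(x)
  o <- order(x)
  xs <- x[o]
  cs <- cumsum(xs); tot <- cs[n]
  k <- seq_len(n - 1)
  ss_left <- cumsum(xs^2)[k] - cs[k]^2 / k
  rest_sum <- tot - cs[k]
  ss_right <- (sum(xs^2) - cumsum(xs^2)[k]) - rest_sum^2 / (n - k)
  best <- which.min(ss_left + ss_right)
  labels <- integer(n)
  labels[o] <- rep(1:2, c(best, n - best))
  labels
}

#' Minor-cluster proportion per population from a genotype PCA
#'
#' Splits all individuals into two clusters by an exact 1-dimensional
#' 2-means on PC1 (sign-invariant), takes the smaller cluster overall as
#' the minor subpopulation, and reports the fraction of each population's
#' individuals falling in it. Degenerate PC1 (zero variance) gives NA.
#'
#' @param pca `pca_result` from [genotype_pca()]
#' @param populations character vector of population ids, one per score row
#' @return named numeric vector of minor-cluster fractions per population,
#'   with attribute "cluster" (per-individual labels, 1 = minor)
#' @export
subpopulation_proportion <- function(pca, populations) {
  pc1 <- pca$scores[, 1]
  if (length(populations) != length(pc1))
    stop("need one population label per individual")
  if (stats::sd(pc1) < 1e-12) {
    out <- stats::setNames(rep(NA_real_, length(unique(populations))),
                           unique(populations))
    return(out)
  }
  lab <- split_1d_2means(pc1)
  minor <- if (sum(lab == 1) <= sum(lab == 2)) 1L else 2L
  in_minor <- lab == minor
  out <- tapply(in_minor, populations, mean)
  res <- stats::setNames(as.numeric(out), names(out))
  attr(res, "cluster") <- ifelse(in_minor, 1L, 2L)
  res
}

#' Write PCA scores and variance fractions as TSV
#' @param pca pca_result
#' @param path output path
#' @param ids entity ids (default rownames of scores)
#' @param n_components components to keep (default 3)
#' @export
write_pca <- function(pca, path, ids = rownames(pca$scores),
                      n_components = 3) {
  k <- min(n_components, ncol(pca$scores))
  out <- data.frame(id = ids, pca$scores[, seq_len(k), drop = FALSE])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  vf_path <- sub("(\\.[^.]*)?$", "_variance\\1", path)
  utils::write.table(
    data.frame(component = seq_along(pca$variance_fraction),
               variance_fraction = pca$variance_fraction),
    vf_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
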