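#' Balanced two-way fixed-effects ANOVA of one SNP's allele frequencies
#'
#' Classical decomposition for a balanced 2x2 design (stand type x seeding
#' density with replicate plots as error): sums of squares for the two
#' main effects and their interaction, each on 1 df, F against the
#' residual mean square on (total - 4) df. In the balanced case type-I and
#' type-III sums of squares coincide and
#' `SS_total = SS_stand + SS_density + SS_interaction + SS_error`. When
#' all responses are equal every p is 1 by convention.
#'
#' @param q numeric vector of per-plot allele frequencies, one per
#'   population/plot
#' @param design data.frame with one row per entry of `q` and columns
#'   `stand` and `density` (two levels each, equal replication per cell,
#'   at least 2 replicates)
#' @return one-row data.frame of class `anova_row` with sums of squares, F
#'   statistics and p-values for stand, density and interaction
#' @export
two_way_anova <- function(q, design) {
  design <- as.data.frame(design)
  stopifnot(length(q) == nrow(design),
            all(c("stand", "density") %in% names(design)))
  stand <- factor(design$stand); density <- factor(design$density)
  if (nlevels(stand) != 2 || nlevels(density) != 2)
    stop("balanced-only contract: need exactly two levels per factor")
  cell_n <- table(stand, density)
  if (length(unique(as.vector(cell_n))) != 1 || any(cell_n < 2))
    stop("balanced-only contract: equal replication (>= 2) in every cell ",
         "is required; average replicate pools per plot first")
  fit <- stats::lm(q ~ stand * density)
  an <- suppressWarnings(stats::anova(fit))  # perfect-fit warning; p := 1 below
  ss <- an[["Sum Sq"]]; names(ss) <- rownames(an)
  df_err <- an["Residuals", "Df"]
  ms_err <- ss[["Residuals"]] / df_err
  # guard against numerically-zero decompositions (all responses equal)
  eps <- 1e-12 * max(1, mean(q)^2)
  f_of <- function(term) {
    if (ms_err <= eps) {
      if (ss[[term]] <= eps) return(c(f = 0, p = 1))
      return(c(f = Inf, p = 0))
    }
    f <- (ss[[term]] / 1) / ms_err
    c(f = f, p = stats::pf(f, 1, df_err, lower.tail = FALSE))
  }
  st <- f_of("stand"); de <- f_of("density"); int <- f_of("stand:density")
  out <- data.frame(
    ss_stand = ss[["stand"]], ss_density = ss[["density"]],
    ss_interaction = ss[["stand:density"]], ss_error = ss[["Residuals"]],
    df_error = df_err,
    f_stand = st["f"], f_density = de["f"], f_interaction = int["f"],
    p_stand = st["p"], p_density = de["p"], p_interaction = int["p"],
    row.names = NULL
  )
  class(out) <- c("anova_row", "data.frame")
  out
}

#' Two-way ANOVA over a candidate SNP list
#'
#' Runs [two_way_anova()] on each candidate SNP of a per-plot frequency
#' table (replicate pools must already be averaged per plot) and appends
#' the absolute difference in mean frequency between the levels of each
#' factor, plus conventional significance stars (*, **, *** for 0.05,
#' 0.01, 0.001).
#'
#' @param f freq_table with plots as populations
#' @param design data.frame with columns `population_id`, `stand`,
#'   `density`
#' @param candidates character vector of SNP ids to test (e.g. an external
#'   outlier program's list); defaults to all SNPs
#' @return data.frame, one row per candidate SNP
#' @export
anova_scan <- function(f, design, candidates = f$snps$snp_id) {
  design <- as.data.frame(design)
  stopifnot(all(c("population_id", "stand", "density") %in% names(design)))
  if (!all(f$populations %in% design$population_id))
    stop("missing treatment metadata for: ",
         paste(setdiff(f$populations, design$population_id), collapse = ", "))
  d <- design[match(f$populations, design$population_id), ]
  unknown <- setdiff(candidates, f$snps$snp_id)
  if (length(unknown))
    stop("candidate SNPs absent from frequency table: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  rows <- lapply(candidates, function(s) {
    q <- f$q[, s]
    ar <- two_way_anova(q, d)
    lev_s <- unique(d$stand); lev_d <- unique(d$density)
    ar$diff_stand <- abs(mean(q[d$stand == lev_s[1]]) -
                           mean(q[d$stand == lev_s[2]]))
    ar$diff_density <- abs(mean(q[d$density == lev_d[1]]) -
                             mean(q[d$density == lev_d[2]]))
    ar
  })
  out <- cbind(data.frame(snp_id = candidates, stringsAsFactors = FALSE),
               do.call(rbind, rows))
  stars <- function(p) ifelse(p < 0.001, "***",
                       ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
  out$sig_stand <- stars(out$p_stand)
  out$sig_density <- stars(out$p_density)
  out$sig_interaction <- stars(out$p_interaction)
  out
}

#' Classify candidate SNPs by which treatment affected them
#'
#' Partition at level `alpha`: significant stand effect only, density
#' effect only, both, or neither. The four class sizes sum to the input
#' size.
#'
#' @param rows data.frame from [anova_scan()] (needs `p_stand`,
#'   `p_density`)
#' @param alpha significance level (default 0.05)
#' @return list with per-SNP `class` factor and `counts`
#' @export
classify_candidates <- function(rows, alpha = 0.05) {
  s <- rows$p_stand < alpha
  d <- rows$p_density < alpha
  cls <- factor(ifelse(s & d, "both",
                ifelse(s, "stand_only",
                ifelse(d, "density_only", "neither"))),
                levels = c("stand_only", "density_only", "both", "neither"))
  list(class = stats::setNames(cls, rows$snp_id), counts = table(cls))
}
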