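#' Simulator configuration
#'
#' Defines the study conditions the synthetic data emulates: an outbred
#' base population with weak two-subpopulation structure, replicate field
#' plots in which most mortality is random but a handful of loci carry
#' genotype-dependent survival, GBS sequencing of sampled individuals, and
#' pooled (DNA or leaf) sequencing of whole samples.
#'
#' Defaults: 2000 loci, base frequencies uniform on [0.05, 0.95], minor
#' subpopulation fraction 0.17 at divergence F_ST 0.02 between the two
#' subpopulations; per plot 2000 sown plants of which ~500 survive
#' (survival fraction ~0.25, in the range observed in dense pure stands
#' after 2-3 seasons); 4 replicate plots; 88 individuals sampled from the
#' original population and 48 from each survivor population; GBS depth
#' negative-binomial with mean 30 (dispersion size 5) and sequencing error
#' 0.005; pools of 100 individuals at nominal 200 gametes, pool depth
#' negative-binomial mean 250, leaf pools with Dirichlet tissue-amount
#' noise (concentration 1, i.e. strongly uneven leaf sizes, reproducing replicate leaf-pool deviations near 0.05), and a phenomenological high-depth
#' contamination term above 600 reads.
#'
#' @param seed integer; the single source of randomness.
#' @param L number of loci.
#' @param n_selected loci under selection (selected loci are the first
#'   `n_selected` indices unless `selected_loci` is given).
#' @param survival_probs matrix `n_selected x 3` of genotype survival
#'   probabilities (p0, p1, p2) for dosage 0/1/2 at each selected locus;
#'   default additive `(0.5, 0.75, 1)` rows.
#' @param selected_loci optional integer indices of the selected loci.
#' @param base_freq_range interval for the base tracked-allele frequency
#'   (truncated so MAF > 0.05).
#' @param minor_fraction proportion of individuals in the minor
#'   subpopulation.
#' @param fst0 target pairwise divergence between the two subpopulations.
#' @param N_sown,N_survivors sown plants and expected survivors per plot.
#' @param n_plots replicate survivor plots (study-1 layout).
#' @param sample_n_original,sample_n_survivor individuals sampled.
#' @param depth_mean,depth_dispersion negative-binomial GBS read depth per
#'   call (mu, size).
#' @param seq_error per-read sequencing error probability.
#' @param pool_n individuals contributing to a pool.
#' @param pool_depth_mean,pool_depth_dispersion negative-binomial pooled
#'   read depth per SNP (mu, size) for leaf-pool samples.
#' @param dna_pool_depth_mean negative-binomial depth mean per replicate
#'   DNA-pool library (several libraries are merged downstream).
#' @param leaf_concentration Dirichlet concentration of leaf-pool tissue
#'   contributions (equal contributions as concentration -> Inf).
#' @param high_depth_cutoff read depth above which the contamination
#'   artifact applies.
#' @param high_depth_beta shape1/shape2 of the Beta-distributed
#'   contamination fraction above the cutoff.
#' @return list of class `sim_config`
#' @export
sim_config <- function(seed = 1L, L = 2000L, n_selected = 0L,
                       survival_probs = NULL, selected_loci = NULL,
                       base_freq_range = c(0.05, 0.95),
                       minor_fraction = 0.17, fst0 = 0.02,
                       N_sown = 2000L, N_survivors = 500L, n_plots = 4L,
                       sample_n_original = 88L, sample_n_survivor = 48L,
                       depth_mean = 30, depth_dispersion = 5,
                       seq_error = 0.005,
                       pool_n = 100L, pool_depth_mean = 250,
                       pool_depth_dispersion = 3,
                       dna_pool_depth_mean = 40,
                       leaf_concentration = 1,
                       high_depth_cutoff = 600,
                       high_depth_beta = c(1, 4)) {
  if (is.null(selected_loci) && n_selected > 0)
    selected_loci <- seq_len(n_selected)
  if (!is.null(selected_loci)) n_selected <- length(selected_loci)
  if (is.null(survival_probs) && n_selected > 0)
    survival_probs <- matrix(rep(c(0.5, 0.75, 1), each = n_selected),
                             nrow = n_selected)
  if (n_selected > 0) {
    survival_probs <- matrix(survival_probs, ncol = 3)
    stopifnot(nrow(survival_probs) == n_selected,
              all(survival_probs >= 0 & survival_probs <= 1))
  }
  stopifnot(N_survivors <= N_sown, minor_fraction >= 0, minor_fraction <= 1,
            fst0 >= 0, leaf_concentration > 0, seq_error >= 0, seq_error < 0.5)
  structure(list(
    seed = as.integer(seed), L = as.integer(L), n_selected = n_selected,
    survival_probs = survival_probs, selected_loci = selected_loci,
    base_freq_range = base_freq_range, minor_fraction = minor_fraction,
    fst0 = fst0, N_sown = as.integer(N_sown),
    N_survivors = as.integer(N_survivors), n_plots = as.integer(n_plots),
    sample_n_original = as.integer(sample_n_original),
    sample_n_survivor = as.integer(sample_n_survivor),
    depth_mean = depth_mean, depth_dispersion = depth_dispersion,
    seq_error = seq_error, pool_n = as.integer(pool_n),
    pool_depth_mean = pool_depth_mean,
    pool_depth_dispersion = pool_depth_dispersion,
    dna_pool_depth_mean = dna_pool_depth_mean,
    leaf_concentration = leaf_concentration,
    high_depth_cutoff = high_depth_cutoff,
    high_depth_beta = high_depth_beta
  ), class = "sim_config")
}

#' Draw base and subpopulation allele frequencies
#'
#' Tracked-allele base frequencies are uniform on `base_freq_range`
#' (re-drawn until MAF > 0.05). The two subpopulation frequency vectors
#' are drawn around the base by a Balding-Nichols beta model with drift
#' parameter `2 * fst0`, which yields an expected pairwise F_ST between
#' the two subpopulations of about `fst0`; draws leaving a subpopulation
#' effectively monomorphic are re-drawn.
#'
#' @param cfg sim_config
#' @return list: `base_q` (length L), `sub_q` (2 x L), `selected_loci`,
#'   `survival_probs`
#' @export
draw_base_frequencies <- function(cfg) {
  lo <- max(cfg$base_freq_range[1], 0.05 + 1e-9)
  hi <- min(cfg$base_freq_range[2], 0.95 - 1e-9)
  q0 <- stats::runif(cfg$L, lo, hi)
  if (cfg$fst0 > 0) {
    Fd <- 2 * cfg$fst0
    a <- q0 * (1 - Fd) / Fd
    b <- (1 - q0) * (1 - Fd) / Fd
    draw <- function() rbind(stats::rbeta(cfg$L, a, b),
                             stats::rbeta(cfg$L, a, b))
    sub_q <- draw()
    for (it in 1:20) {                       # re-draw near-fixed loci
      bad <- sub_q < 1e-4 | sub_q > 1 - 1e-4
      if (!any(bad)) break
      cols <- unique(((which(bad) - 1) %/% 2) + 1)
      sub_q[, cols] <- draw()[, cols]
    }
  } else {
    sub_q <- rbind(q0, q0)
  }
  dimnames(sub_q) <- NULL
  list(base_q = q0, sub_q = sub_q, selected_loci = cfg$selected_loci,
       survival_probs = cfg$survival_probs)
}

#' Simulate a sown cohort from the base population
#'
#' Individuals belong to the minor subpopulation with probability
#' `minor_fraction`; genotypes are Hardy-Weinberg draws from the
#' individual's subpopulation frequencies. Dosages are exact (no read
#' noise); depths are set to a constant consistent with the dosage so the
#' cohort passes the call filters unchanged.
#'
#' @param cfg sim_config
#' @param n cohort size (default `N_sown`)
#' @param truth frequency draw from [draw_base_frequencies()]; drawn fresh
#'   (after seeding from `cfg$seed`) when NULL
#' @param population_id label for the cohort
#' @return list: `genotypes` (genotype_matrix), `truth` (with
#'   `subpop` labels appended)
#' @export
simulate_base_population <- function(cfg, n = cfg$N_sown, truth = NULL,
                                     population_id = "base") {
  if (is.null(truth)) {
    set.seed(cfg$seed)
    truth <- draw_base_frequencies(cfg)
  }
  subpop <- 1L + (stats::runif(n) < cfg$minor_fraction)
  qmat <- truth$sub_q[subpop, , drop = FALSE]          # n x L
  dosage <- matrix(stats::rbinom(n * cfg$L, 2L, qmat), n, cfg$L)
  g <- perfect_depth_genotypes(dosage, population_id)
  truth$subpop <- subpop
  list(genotypes = g, truth = truth)
}

# wrap a dosage matrix as a genotype_matrix with clean, filter-passing depths
perfect_depth_genotypes <- function(dosage, population_id,
                                    snp_ids = paste0("snp", seq_len(ncol(dosage)))) {
  n <- nrow(dosage)
  ids <- paste0(population_id, "_", seq_len(n))
  dref <- matrix(15L * (2L - dosage), n, ncol(dosage))
  dalt <- matrix(15L * dosage, n, ncol(dosage))
  genotype_matrix(
    snp_records(snp_ids),
    data.frame(individual_id = ids, population_id = population_id,
               stringsAsFactors = FALSE),
    dosage, dref, dalt)
}

#' Apply within-generation viability selection to a cohort
#'
#' Each individual survives independently with probability proportional to
#' the product over selected loci of its genotype survival probability,
#' scaled so the expected survivor count equals `N_survivors` (capped at
#' 1). Neutral loci have survival multiplier 1, so with no selected loci
#' this is pure random mortality and survivor allele frequencies differ
#' from the cohort only by drift. No reproduction or migration.
#'
#' @param cohort genotype_matrix of sown individuals
#' @param cfg sim_config (`selected_loci`, `survival_probs`)
#' @param N_survivors expected survivor count (default from cfg)
#' @return genotype_matrix of survivors
#' @export
apply_viability_selection <- function(cohort, cfg,
                                      N_survivors = cfg$N_survivors) {
  n <- nrow(cohort$dosage)
  w <- rep(1, n)
  if (cfg$n_selected > 0) {
    for (k in seq_len(cfg$n_selected)) {
      loc <- cfg$selected_loci[k]
      w <- w * cfg$survival_probs[k, cohort$dosage[, loc] + 1L]
    }
  }
  if (all(w == 0)) stop("all-zero survival weights")
  p <- scale_survival_probs(w, N_survivors)
  keep <- stats::runif(n) < p
  subset_genotypes(cohort, individuals = keep)
}

# p_i = min(1, c * w_i) with c solved so that sum(p) = N exactly: when the
# fittest individuals hit the probability cap, c is re-solved over the rest
# (water-filling), keeping both the expected survivor count and the
# proportionality of uncapped survival correct under strong selection
scale_survival_probs <- function(w, N) {
  if (N >= length(w)) return(rep(1, length(w)))
  o <- order(w, decreasing = TRUE)
  ws <- w[o]
  n <- length(ws)
  rest <- sum(ws) - c(0, cumsum(ws)[-n])    # sum of w below each cap count
  c_try <- (N - (seq_len(n) - 1)) / rest
  m <- which(c_try * ws <= 1)[1] - 1L       # caps needed before c is valid
  cc <- c_try[m + 1L]
  p <- pmin(1, cc * w)
  if (m > 0) p[o[seq_len(m)]] <- 1
  p
}

#' Expected post-selection allele frequency (closed form)
#'
#' Deterministic single-locus viability-selection expectation
#' `q' = (q^2 p2 + q(1-q) p1) / (q^2 p2 + 2 q(1-q) p1 + (1-q)^2 p0)`
#' under Hardy-Weinberg genotype proportions in the infinite-population
#' limit.
#'
#' @param q pre-selection frequency of the tracked allele
#' @param p0,p1,p2 survival probabilities of dosage-0/1/2 genotypes
#' @return expected survivor frequency
#' @export
expected_post_selection_q <- function(q, p0, p1, p2) {
  num <- q^2 * p2 + q * (1 - q) * p1
  den <- q^2 * p2 + 2 * q * (1 - q) * p1 + (1 - q)^2 * p0
  num / den
}

#' Simulate GBS reads and re-call genotypes
#'
#' Per call, total depth is negative-binomial (`depth_mean`,
#' `depth_dispersion`); alt reads are binomial with success probability
#' `dosage/2` moved toward the other allele by the sequencing error rate.
#' Dosage is then re-called naively from the reads (both alleles seen =
#' heterozygote, one allele = homozygote, no reads = missing), so that the
#' downstream call filters produce realistic missingness.
#'
#' @param g genotype_matrix with true dosages
#' @param cfg sim_config
#' @return genotype_matrix with simulated depths and re-called dosages
#' @export
simulate_gbs_reads <- function(g, cfg) {
  n <- nrow(g$dosage); L <- ncol(g$dosage)
  depth <- matrix(stats::rnbinom(n * L, mu = cfg$depth_mean,
                                 size = cfg$depth_dispersion), n, L)
  e <- cfg$seq_error
  f <- g$dosage / 2 * (1 - 2 * e) + e
  alt <- matrix(stats::rbinom(n * L, depth, f), n, L)
  ref <- depth - alt
  recall <- ifelse(depth == 0L, NA_integer_,
            ifelse(alt == 0L, 0L, ifelse(ref == 0L, 2L, 1L)))
  genotype_matrix(g$snps, g$individuals, recall, ref, alt)
}

#' Simulate pooled sequencing of a sample
#'
#' The pooled alt-read fraction at a SNP is the contribution-weighted mean
#' of the individuals' `dosage / 2`; contributions are equal for DNA pools
#' and Dirichlet-distributed (concentration `leaf_concentration`) for leaf
#' pools, emulating unequal tissue amounts. Read depth at a SNP is Poisson
#' around `depth_mean` times a per-SNP tag-abundance factor
#' (Gamma-distributed with shape and rate `depth_dispersion`), shared
#' across replicate libraries: GBS tag depth is overdispersed marginally
#' (negative binomial) but strongly correlated between libraries because
#' restriction-site quality is a property of the locus. Reads are binomial
#' at the (sequencing-error-adjusted) pooled fraction. Above
#' `high_depth_cutoff` reads, a Beta-distributed contamination fraction
#' pulls the read fraction toward 0.5 (collapsed paralogous tags),
#' degrading accuracy at extreme depths.
#'
#' @param g genotype_matrix of the pooled individuals (true dosages)
#' @param cfg sim_config
#' @param mode "dna_pool" (equal contributions) or "leaf_pool"
#' @param n_replicates replicate libraries/pools to draw (>= 1)
#' @param pool_id base id for the pool
#' @param population_id population label (default from `g`)
#' @param depth_mean,depth_dispersion depth law; the mean defaults to the
#'   leaf-pool depth for leaf pools and to the per-library DNA-pool depth
#'   otherwise
#' @param snp_depth_factor optional per-SNP tag-abundance factors; pass
#'   one vector to several calls to make depth profiles consistent across
#'   pools of different populations (drawn fresh when NULL)
#' @return pool_count_table with one row per replicate library
#' @export
simulate_pool_reads <- function(g, cfg, mode = c("dna_pool", "leaf_pool"),
                                n_replicates = 1L, pool_id = "pool1",
                                population_id = g$individuals$population_id[1],
                                depth_mean = NULL,
                                depth_dispersion = cfg$pool_depth_dispersion,
                                snp_depth_factor = NULL) {
  mode <- match.arg(mode)
  if (is.null(depth_mean))
    depth_mean <- if (mode == "leaf_pool") cfg$pool_depth_mean else
      cfg$dna_pool_depth_mean
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  n <- nrow(g$dosage); L <- ncol(g$dosage)
  if (is.null(snp_depth_factor))
    snp_depth_factor <- stats::rgamma(L, shape = depth_dispersion,
                                      rate = depth_dispersion)
  # paralog collapse is a locus property: loci whose expected depth after
  # merging exceeds the cutoff carry a contamination fraction pulling the
  # read fraction toward 0.5, identically in every replicate library
  merge_mult <- if (mode == "dna_pool") n_replicates else 1L
  hi <- depth_mean * merge_mult * snp_depth_factor > cfg$high_depth_cutoff
  contam <- numeric(L)
  if (any(hi))
    contam[hi] <- stats::rbeta(sum(hi), cfg$high_depth_beta[1],
                               cfg$high_depth_beta[2])
  e <- cfg$seq_error
  cr <- matrix(0L, n_replicates, L); ca <- cr
  for (r in seq_len(n_replicates)) {
    w <- if (mode == "dna_pool") rep(1 / n, n) else {
      ww <- stats::rgamma(n, shape = cfg$leaf_concentration)
      ww / sum(ww)
    }
    frac <- as.numeric(crossprod(w, g$dosage / 2))
    frac <- frac * (1 - 2 * e) + e
    frac <- (1 - contam) * frac + contam * 0.5
    depth <- stats::rpois(L, depth_mean * snp_depth_factor)
    alt <- stats::rbinom(L, depth, frac)
    cr[r, ] <- depth - alt
    ca[r, ] <- alt
  }
  pool_count_table(
    pools = data.frame(pool_id = pool_id, population_id = population_id,
                       replicate_index = seq_len(n_replicates),
                       library_id = paste0(pool_id, "_lib",
                                           seq_len(n_replicates)),
                       stringsAsFactors = FALSE),
    snps = g$snps, counts_ref = cr, counts_alt = ca)
}

#' Simulate a complete survivor-population experiment
#'
#' Generates, from one seed, every input the pipeline consumes:
#' \describe{
#'   \item{study-1 layout}{an original-population sample plus `n_plots`
#'     replicate survivor-plot samples with individual GBS data (shared
#'     selected loci in every plot);}
#'   \item{study-2 layout}{replicate DNA-pool libraries of the original
#'     sample;}
#'   \item{study-3 layout}{8 leaf-pool populations in a 2x2 treatment
#'     design (pure/mixed stand x high/low density, 2 replicate plots per
#'     cell), with stand-specific and density-specific selected loci
#'     applied only in the pure-stand or high-density plots respectively;
#'     the first pure-stand high-density plots carry 3 replicate pools.}
#' }
#' Ground truth (selected loci, survival probabilities, base and
#' subpopulation frequencies, expected post-selection frequencies) is
#' returned alongside.
#'
#' @param cfg sim_config
#' @param gbs_reads simulate GBS read noise and re-call genotypes for the
#'   study-1 samples (TRUE) or keep exact dosages (FALSE)
#' @param study3 also generate the study-3 pooled layout
#' @param n_stand_loci,n_density_loci selected loci specific to stand type
#'   / seeding density in the study-3 layout (taken from loci after the
#'   shared selected ones)
#' @param treatment_survival genotype survival probabilities (p0, p1, p2)
#'   of the stand- and density-specific loci in the plots where they act
#' @param n_pool_replicates replicate DNA-pool libraries for study 2
#' @param write_dir optional directory: writes all tables in the package
#'   formats (genotypes TSV, pool counts TSV, metadata TSV, truth TSV)
#' @return list with `study1` (genotypes, pops), `study2` (pool_counts),
#'   `study3` (pool_counts, design, groups) or NULL, and `truth`
#' @export
simulate_experiment <- function(cfg, gbs_reads = FALSE, study3 = FALSE,
                                n_stand_loci = 0L, n_density_loci = 0L,
                                treatment_survival = c(0.5, 0.75, 1),
                                n_pool_replicates = 7L, write_dir = NULL) {
  set.seed(cfg$seed)
  truth <- draw_base_frequencies(cfg)

  ## -- study 1: original sample + replicate survivor plots --------------
  orig <- simulate_base_population(cfg, n = cfg$sample_n_original,
                                   truth = truth, population_id = "original")
  samples <- list(orig$genotypes)
  truth$subpop_original <- orig$truth$subpop
  expected_q <- NULL
  if (cfg$n_selected > 0) {
    sp <- cfg$survival_probs
    q0 <- truth$base_q[cfg$selected_loci]
    expected_q <- expected_post_selection_q(q0, sp[, 1], sp[, 2], sp[, 3])
  }
  for (pl in seq_len(cfg$n_plots)) {
    cohort <- simulate_base_population(
      cfg, n = cfg$N_sown, truth = truth,
      population_id = paste0("survivor", pl))$genotypes
    surv <- apply_viability_selection(cohort, cfg)
    take <- sample(nrow(surv$dosage),
                   min(cfg$sample_n_survivor, nrow(surv$dosage)))
    samples[[pl + 1]] <- subset_genotypes(surv, individuals = take)
  }
  g1 <- bind_genotypes(samples)
  if (gbs_reads) g1 <- simulate_gbs_reads(g1, cfg)
  pops1 <- population_meta(
    population_id = c("original", paste0("survivor", seq_len(cfg$n_plots))),
    role = c("original", rep("survivor", cfg$n_plots)),
    stand_type = c(NA, rep("pure", cfg$n_plots)),
    seeding_density = c(NA, rep("high", cfg$n_plots)),
    harvest_regime = c(NA, rep("3H", cfg$n_plots)),
    replicate_plot = c(NA, seq_len(cfg$n_plots)),
    n_sampled = c(cfg$sample_n_original, rep(cfg$sample_n_survivor,
                                             cfg$n_plots)))

  ## -- study 2: replicate DNA-pool libraries of the original sample -----
  pool2 <- simulate_pool_reads(orig$genotypes, cfg, mode = "dna_pool",
                               n_replicates = n_pool_replicates,
                               pool_id = "orig_dna_pool",
                               population_id = "original")

  # tag abundance is a property of the locus: one factor vector shared by
  # every pooled sample of the study-3 layout
  depth_factor3 <- stats::rgamma(cfg$L, shape = cfg$pool_depth_dispersion,
                                 rate = cfg$pool_depth_dispersion)

  ## -- study 3: 8 leaf-pool populations, 2x2 treatment design -----------
  s3 <- NULL
  if (study3) {
    base_sel <- if (is.null(cfg$selected_loci)) integer(0) else
      cfg$selected_loci
    next_free <- if (length(base_sel)) max(base_sel) else 0L
    stand_loci <- seq_len(n_stand_loci) + next_free
    density_loci <- seq_len(n_density_loci) + next_free + n_stand_loci
    stopifnot(length(stand_loci) == 0 || max(stand_loci) <= cfg$L,
              length(density_loci) == 0 || max(density_loci) <= cfg$L)
    design <- expand.grid(stand = c("pure", "mixed"),
                          density = c("high", "low"),
                          rep = 1:2, stringsAsFactors = FALSE)
    design$population_id <- sprintf(
      "%s_%s_%d", ifelse(design$stand == "pure", "Ps", "Ms"),
      ifelse(design$density == "high", "H", "L"), design$rep)
    tabs <- vector("list", nrow(design))
    truth$expected_q_study3 <- list()
    for (i in seq_len(nrow(design))) {
      sel <- c(base_sel,
               if (design$stand[i] == "pure") stand_loci else integer(0),
               if (design$density[i] == "high") density_loci else integer(0))
      cfg_i <- cfg
      cfg_i$selected_loci <- sel
      cfg_i$n_selected <- length(sel)
      cfg_i$survival_probs <- if (length(sel))
        rbind(cfg$survival_probs[match(base_sel, cfg$selected_loci), ,
                                 drop = FALSE],
              matrix(rep(treatment_survival,
                         each = length(sel) - length(base_sel)),
                     ncol = 3)) else NULL
      cohort <- simulate_base_population(
        cfg, n = cfg$N_sown, truth = truth,
        population_id = design$population_id[i])$genotypes
      surv <- apply_viability_selection(cohort, cfg_i)
      take <- sample(nrow(surv$dosage), min(cfg$pool_n, nrow(surv$dosage)))
      pooled_ind <- subset_genotypes(surv, individuals = take)
      n_rep <- if (design$stand[i] == "pure" && design$density[i] == "high")
        3L else 1L
      tabs[[i]] <- simulate_pool_reads(
        pooled_ind, cfg, mode = "leaf_pool", n_replicates = n_rep,
        pool_id = design$population_id[i],
        population_id = design$population_id[i],
        snp_depth_factor = depth_factor3)
    }
    s3 <- list(pool_counts = bind_pool_tables(tabs),
               design = design[c("population_id", "stand", "density")],
               stand_loci = stand_loci, density_loci = density_loci)
  }

  truth$expected_q_selected <- expected_q
  out <- list(study1 = list(genotypes = g1, pops = pops1),
              study2 = list(pool_counts = pool2),
              study3 = s3, truth = truth, config = cfg)
  if (!is.null(write_dir)) write_experiment(out, write_dir)
  out
}

# row-bind genotype matrices sharing one SNP panel
bind_genotypes <- function(gs) {
  snps <- gs[[1]]$snps
  genotype_matrix(
    snps,
    do.call(rbind, lapply(gs, `[[`, "individuals")),
    do.call(rbind, lapply(gs, `[[`, "dosage")),
    do.call(rbind, lapply(gs, `[[`, "depth_ref")),
    do.call(rbind, lapply(gs, `[[`, "depth_alt")))
}

# row-bind pool count tables sharing one SNP panel
bind_pool_tables <- function(ps) {
  pool_count_table(
    do.call(rbind, lapply(ps, `[[`, "pools")),
    ps[[1]]$snps,
    do.call(rbind, lapply(ps, `[[`, "counts_ref")),
    do.call(rbind, lapply(ps, `[[`, "counts_alt")))
}

# serialize a simulated experiment in the package's file formats
write_experiment <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(sim$study1$genotypes, file.path(dir, "study1_genotypes.tsv"))
  utils::write.table(sim$study1$pops, file.path(dir, "study1_populations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_pool_counts(sim$study2$pool_counts,
                    file.path(dir, "study2_pool_counts.tsv"))
  if (!is.null(sim$study3)) {
    write_pool_counts(sim$study3$pool_counts,
                      file.path(dir, "study3_pool_counts.tsv"))
    utils::write.table(sim$study3$design, file.path(dir, "study3_design.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  sel <- sim$config$selected_loci
  truth_df <- data.frame(
    snp_id = sim$study1$genotypes$snps$snp_id,
    base_q = sim$truth$base_q,
    selected = seq_along(sim$truth$base_q) %in% sel
  )
  if (!is.null(sim$truth$expected_q_selected)) {
    truth_df$expected_q <- NA_real_
    truth_df$expected_q[sel] <- sim$truth$expected_q_selected
  }
  utils::write.table(truth_df, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
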