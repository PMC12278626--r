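#' Line-model category labels
#'
#' Category labels used throughout the package for the mixture of effect-size
#' sharing patterns between the prenatal and adult datasets, in the canonical
#' order: `null` (no sex effect), `PRENATAL` (prenatal-specific), `SHARED0.5`
#' (shared, adult effect half the prenatal one), `SHARED1` (shared, equal),
#' `SHARED2` (shared, adult effect twice the prenatal one), `ADULT`
#' (adult-specific), `OPPOSITE` (equal magnitude, opposite sign).
#'
#' @export
SIM_CATEGORIES <- c("null", "PRENATAL", "SHARED0.5", "SHARED1", "SHARED2",
                    "ADULT", "OPPOSITE")

#' Simulation configuration
#'
#' Builds a validated configuration for the synthetic two-cohort generator.
#' Defaults emulate the study conditions the package targets: a prenatal
#' cohort with a strong developmental trajectory and an adult cohort without
#' one, repeated samples per individual, XIST-like and chromosome-Y marker
#' genes for sex assignment, and gene-level sex effects drawn from a known
#' mixture of sharing categories.
#'
#' @param n_genes number of non-marker genes.
#' @param n_individuals_per_stage number of individuals per cohort.
#' @param samples_per_individual integer range `c(min, max)`; each individual
#'   contributes a uniform draw from this range.
#' @param sex_ratio fraction of individuals that are female.
#' @param category_proportions 7-vector over [SIM_CATEGORIES] summing to 1.
#'   The default mirrors the mixture recovered on real forebrain data:
#'   mostly prenatal-specific, a large shared block dominated by effects twice
#'   as large prenatally, and small adult-specific/opposite fractions.
#' @param effect_magnitude standard deviation (log2 units) of the zero-mean
#'   normal from which the driving effect of each non-null gene is drawn;
#'   the default 0.35 gives a mean |logFC| of about 0.28, the scale observed
#'   in prenatal forebrain.
#' @param pseudotime_effect_sd sd (log2 units) of per-gene developmental-time
#'   effects in the prenatal cohort.
#' @param nb_dispersion negative-binomial dispersion (1/size) of the counts.
#' @param library_size_range range of per-sample library sizes (counts).
#' @param n_marker_genes_y number of chrY-like male-only marker genes.
#' @param n_x_genes number of genes placed on the X chromosome.
#' @param n_escape_genes number of X genes simulated as XCI escapees: forced
#'   into female-biased `SHARED1` effects.
#' @param se_range range of per-gene effect standard errors for
#'   [simulate_effect_pairs()]; drawn log-uniformly.
#' @param interaction_sd sd of per-gene sex-by-time interaction effects
#'   (default 0: interactions are rare in the data the generator emulates).
#' @param seed integer seed; a fixed seed yields byte-identical output.
#'
#' @return An object of class `simulation_config` (a named list).
#' @export
simulation_config <- function(n_genes = 2000,
                              n_individuals_per_stage = 60,
                              samples_per_individual = c(1L, 3L),
                              sex_ratio = 0.5,
                              category_proportions = c(
                                null = 0.055, PRENATAL = 0.60,
                                "SHARED0.5" = 0.28, SHARED1 = 0.02,
                                SHARED2 = 0.0, ADULT = 0.005,
                                OPPOSITE = 0.04),
                              effect_magnitude = 0.35,
                              pseudotime_effect_sd = 0.7,
                              nb_dispersion = 0.05,
                              library_size_range = c(1e6, 2e6),
                              n_marker_genes_y = 10,
                              n_x_genes = 80,
                              n_escape_genes = 20,
                              se_range = c(0.02, 0.2),
                              interaction_sd = 0,
                              seed = 1L) {
  if (length(category_proportions) != length(SIM_CATEGORIES)) {
    .stopf("category_proportions must have %d entries", length(SIM_CATEGORIES))
  }
  .check_prob_vector(category_proportions, "category_proportions")
  for (v in c("n_genes", "n_individuals_per_stage", "n_marker_genes_y")) {
    if (get(v) <= 0) .stopf("%s must be positive", v)
  }
  if (n_escape_genes > n_x_genes || n_x_genes > n_genes) {
    .stopf("need n_escape_genes <= n_x_genes <= n_genes")
  }
  stopifnot(length(samples_per_individual) == 2,
            samples_per_individual[1] >= 1,
            samples_per_individual[2] >= samples_per_individual[1],
            sex_ratio > 0, sex_ratio < 1,
            effect_magnitude > 0, nb_dispersion > 0,
            length(library_size_range) == 2, all(library_size_range > 0),
            length(se_range) == 2, all(se_range > 0),
            interaction_sd >= 0)
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_individuals_per_stage = as.integer(n_individuals_per_stage),
    samples_per_individual = as.integer(samples_per_individual),
    sex_ratio = sex_ratio,
    category_proportions = stats::setNames(as.numeric(category_proportions),
                                           SIM_CATEGORIES),
    effect_magnitude = effect_magnitude,
    pseudotime_effect_sd = pseudotime_effect_sd,
    nb_dispersion = nb_dispersion,
    library_size_range = as.numeric(library_size_range),
    n_marker_genes_y = as.integer(n_marker_genes_y),
    n_x_genes = as.integer(n_x_genes),
    n_escape_genes = as.integer(n_escape_genes),
    se_range = as.numeric(se_range),
    interaction_sd = interaction_sd,
    seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

# Effect pair implied by a category and its driving effect size.
# Geometry: PRENATAL (b, 0); SHAREDr (b, r*b); ADULT (0, b); OPPOSITE (b, -b).
#' @keywords internal
#' @noRd
.category_betas <- function(category, b) {
  switch(category,
         "null"      = c(0, 0),
         "PRENATAL"  = c(b, 0),
         "SHARED0.5" = c(b, 0.5 * b),
         "SHARED1"   = c(b, b),
         "SHARED2"   = c(b, 2 * b),
         "ADULT"     = c(0, b),
         "OPPOSITE"  = c(b, -b),
         .stopf("unknown category '%s'", category))
}

# Deterministic per-gene truth shared by both cohorts: category, effect pair,
# time effect, baseline expression, chromosome and XCI class.  Uses its own
# seed stream so that simulate_counts() for the two stages sees identical
# gene-level truth.
#' @keywords internal
#' @noRd
.simulate_gene_truth <- function(config) {
  set.seed(config$seed)
  ng <- config$n_genes
  gene_id <- sprintf("gene%05d", seq_len(ng))
  chromosome <- rep("auto", ng)
  xci_class <- rep("autosomal", ng)
  if (config$n_x_genes > 0) {
    xi <- seq_len(config$n_x_genes)
    chromosome[xi] <- "chrX"
    xci_class[xi] <- "inactive"
    if (config$n_escape_genes > 0) {
      xci_class[seq_len(config$n_escape_genes)] <- "escape"
    }
  }
  category <- sample(SIM_CATEGORIES, ng, replace = TRUE,
                     prob = config$category_proportions)
  draw <- stats::rnorm(ng, 0, config$effect_magnitude)
  # XCI escapees: lifelong female-biased expression of the same magnitude in
  # both life stages.
  esc <- xci_class == "escape"
  category[esc] <- "SHARED1"
  draw[esc] <- abs(draw[esc])
  betas <- t(vapply(seq_len(ng),
                    function(i) .category_betas(category[i], draw[i]),
                    numeric(2)))
  delta <- stats::rnorm(ng, 0, config$pseudotime_effect_sd)
  interaction <- if (config$interaction_sd > 0) {
    stats::rnorm(ng, 0, config$interaction_sd)
  } else {
    rep(0, ng)
  }
  mu <- stats::runif(ng, 2, 9)
  data.frame(gene_id = gene_id, chromosome = chromosome,
             xci_class = xci_class, true_category = category,
             true_beta_prenatal = betas[, 1], true_beta_adult = betas[, 2],
             true_delta = delta, true_interaction = interaction,
             baseline_log2 = mu, stringsAsFactors = FALSE)
}

#' Simulate observed effect-size pairs with known ground truth
#'
#' Draws, for each gene, a sharing category from the configured mixture, a
#' true effect pair obeying that category's line geometry exactly, per-gene
#' standard errors log-uniform on `config$se_range`, and observed effects
#' `b = beta + N(0, se^2)` independently on the two axes. This is the direct
#' generative counterpart of the six line models, used for parameter-recovery
#' tests of the Bayesian classifier without any count simulation.
#'
#' @param config a [simulation_config()].
#' @return list with `pairs` (data.frame `gene_id, b1, se1, b2, se2`; axis 1 =
#'   prenatal, axis 2 = adult) and `truth` (per-gene category and true betas).
#' @export
simulate_effect_pairs <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  category <- sample(SIM_CATEGORIES, ng, replace = TRUE,
                     prob = config$category_proportions)
  draw <- stats::rnorm(ng, 0, config$effect_magnitude)
  betas <- t(vapply(seq_len(ng),
                    function(i) .category_betas(category[i], draw[i]),
                    numeric(2)))
  lr <- log(config$se_range)
  se1 <- exp(stats::runif(ng, lr[1], lr[2]))
  se2 <- exp(stats::runif(ng, lr[1], lr[2]))
  b1 <- betas[, 1] + stats::rnorm(ng, 0, se1)
  b2 <- betas[, 2] + stats::rnorm(ng, 0, se2)
  gene_id <- sprintf("gene%05d", seq_len(ng))
  list(
    pairs = data.frame(gene_id = gene_id, b1 = b1, se1 = se1,
                       b2 = b2, se2 = se2, stringsAsFactors = FALSE),
    truth = data.frame(gene_id = gene_id, true_category = category,
                       true_beta_prenatal = betas[, 1],
                       true_beta_adult = betas[, 2],
                       stringsAsFactors = FALSE))
}

#' Simulate a negative-binomial RNA-seq cohort with known ground truth
#'
#' Generates one cohort (life stage) of gene-by-sample counts. Individuals
#' receive a sex (female coded 1, so positive logFC means female-biased) and,
#' in the prenatal cohort only, a developmental time `t ~ Uniform(0, 1)`; the
#' adult cohort has no developmental trajectory. Each individual contributes
#' 1 to `samples_per_individual[2]` samples. The log2 mean of gene g in sample
#' n is `mu_g + delta_g * t_n + x_n * beta_stage_g (+ gamma_g * x_n * t_n)`
#' and counts are negative binomial with the configured dispersion and
#' per-sample library sizes. Marker genes are appended: one XIST-like gene
#' expressed only in females and `n_marker_genes_y` chrY-like genes expressed
#' only in males (their counts are exactly zero in the other sex).
#'
#' @param config a [simulation_config()].
#' @param stage `"prenatal"` or `"adult"`.
#' @return list with `counts` (integer matrix, genes x samples), `samples`
#'   (sample metadata: sample_id, individual_id, sex, stage, time, region,
#'   library_size), `genes` (gene table incl. chromosome, xci_class, marker
#'   flags and the true per-gene parameters) and `truth` (the gene table
#'   restricted to truth columns).
#' @export
simulate_counts <- function(config, stage = c("prenatal", "adult")) {
  stopifnot(inherits(config, "simulation_config"))
  stage <- match.arg(stage)
  truth <- .simulate_gene_truth(config)

  # independent, stage-tagged sampling stream (truth stream already consumed)
  set.seed(config$seed + if (stage == "prenatal") 104729L else 224737L)

  nind <- config$n_individuals_per_stage
  sex <- ifelse(stats::runif(nind) < config$sex_ratio, "female", "male")
  t_ind <- if (stage == "prenatal") stats::runif(nind) else rep(0, nind)
  spi <- config$samples_per_individual
  nsamp_ind <- sample(seq(spi[1], spi[2]), nind, replace = TRUE)

  individual_id <- rep(sprintf("%s_ind%03d", stage, seq_len(nind)), nsamp_ind)
  sex_s <- rep(sex, nsamp_ind)
  t_s <- rep(t_ind, nsamp_ind)
  ns <- length(individual_id)
  sample_id <- sprintf("%s_s%04d", stage, seq_len(ns))
  libsize <- stats::runif(ns, config$library_size_range[1],
                          config$library_size_range[2])

  x <- as.numeric(sex_s == "female")
  beta <- if (stage == "prenatal") truth$true_beta_prenatal else
    truth$true_beta_adult
  # genes x samples matrix of log2 relative expression
  ell <- outer(truth$baseline_log2, rep(1, ns)) +
    outer(truth$true_delta, t_s) +
    outer(beta, x) +
    outer(truth$true_interaction, x * t_s)
  base_total <- sum(2^truth$baseline_log2)
  mu <- 2^ell * rep(libsize / base_total, each = nrow(ell))
  size <- 1 / config$nb_dispersion
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = size),
                   nrow = nrow(mu))

  # marker genes: expressed in one sex only, zero in the other
  xist_mu <- 2e-3 * libsize
  chry_mu <- 5e-4 * libsize
  xist <- ifelse(x == 1, stats::rnbinom(ns, mu = xist_mu, size = size), 0L)
  chry <- matrix(0L, nrow = config$n_marker_genes_y, ncol = ns)
  male <- x == 0
  if (any(male)) {
    nm <- sum(male)
    chry[, male] <- matrix(
      stats::rnbinom(config$n_marker_genes_y * nm,
                     mu = rep(chry_mu[male], each = config$n_marker_genes_y),
                     size = size),
      nrow = config$n_marker_genes_y)
  }
  counts <- rbind(counts, matrix(xist, nrow = 1), chry)

  marker_genes <- data.frame(
    gene_id = c("XIST_like", sprintf("chrY_marker%02d",
                                     seq_len(config$n_marker_genes_y))),
    chromosome = c("chrX", rep("chrY", config$n_marker_genes_y)),
    xci_class = "unknown",
    true_category = "null",
    true_beta_prenatal = 0, true_beta_adult = 0,
    true_delta = 0, true_interaction = 0, baseline_log2 = NA_real_,
    stringsAsFactors = FALSE)
  genes <- rbind(truth, marker_genes)
  genes$is_xist <- genes$gene_id == "XIST_like"
  genes$is_chry_marker <- genes$chromosome == "chrY"

  dimnames(counts) <- list(genes$gene_id, sample_id)
  storage.mode(counts) <- "integer"

  samples <- data.frame(
    sample_id = sample_id, individual_id = individual_id, sex = sex_s,
    stage = stage, time = t_s, region = "forebrain",
    library_size = colSums(counts), stringsAsFactors = FALSE)

  list(counts = counts, samples = samples, genes = genes,
       truth = genes[, c("gene_id", "true_category", "true_beta_prenatal",
                         "true_beta_adult", "true_delta")])
}
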