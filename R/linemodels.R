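#' Default prior scale for the line models
#'
#' The prior standard deviation of effect sizes (log2-logFC units) used for
#' all six line models when comparing prenatal and adult forebrain sex-DE:
#' the 95th percentile of the |logFC| of prenatal sex-DE genes divided by 2
#' (see [compute_scale()]). Shipped as a documented constant so analyses can
#' be rerun without the original dataset.
#'
#' @export
LINEMODEL_SCALE_DEFAULT <- 0.1971916

#' A single line model
#'
#' A line model is a hypothesis about a pair of effect sizes
#' `(b_prenatal, b_adult)`, encoded as a thin zero-mean bivariate Gaussian
#' prior concentrated along the line through the origin with the given slope:
#' slope 0 = effect only on the first axis (prenatal-specific), slope `Inf` =
#' only on the second (adult-specific), slope 1 = equal shared effects, 0.5
#' and 2 = shared with a factor-2 magnitude asymmetry, -1 = opposite effects.
#'
#' @param name model label.
#' @param slope line slope (real, or `Inf` for the second-axis model).
#' @param scale prior sd of the effect size along the first axis (the second
#'   axis gets `|slope| * scale`).
#' @param cor how tightly the prior concentrates on the line (correlation
#'   magnitude, < 1); the allowed deviation from the exact line.
#' @return list of class `line_model_spec`.
#' @export
line_model_spec <- function(name, slope, scale = LINEMODEL_SCALE_DEFAULT,
                            cor = 0.995) {
  stopifnot(is.character(name), length(name) == 1, scale > 0)
  if (abs(cor) >= 1) .stopf("|cor| must be < 1")
  structure(list(name = name, slope = slope, scale = scale, cor = cor),
            class = "line_model_spec")
}

#' The six default line models
#'
#' PRENATAL (slope 0), SHARED0.5 (slope 0.5), SHARED1 (slope 1), SHARED2
#' (slope 2), ADULT (slope `Inf`) and OPPOSITE (slope -1). All use the same
#' scale; OPPOSITE uses its own (slightly looser) correlation.
#'
#' @param scale prior effect-size sd for all models.
#' @param cor line concentration for all models except OPPOSITE.
#' @param cor_opposite line concentration for OPPOSITE.
#' @return named list of [line_model_spec()]s.
#' @export
default_line_models <- function(scale = LINEMODEL_SCALE_DEFAULT,
                                cor = 0.995, cor_opposite = 0.990) {
  specs <- list(
    line_model_spec("PRENATAL", 0, scale, cor),
    line_model_spec("SHARED0.5", 0.5, scale, cor),
    line_model_spec("SHARED1", 1, scale, cor),
    line_model_spec("SHARED2", 2, scale, cor),
    line_model_spec("ADULT", Inf, scale, cor),
    line_model_spec("OPPOSITE", -1, scale, cor_opposite))
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Line-model analysis configuration
#'
#' @param models list of [line_model_spec()]s (default the six standard
#'   models).
#' @param r_lkhood correlation between the effect-size estimators of the two
#'   datasets (0 for independent datasets; see [estimate_r_lkhood()] for
#'   overlapping-individual dataset pairs).
#' @param n_iter total Gibbs iterations.
#' @param burn_in burn-in iterations (< `n_iter`).
#' @param dirichlet_prior per-model Dirichlet pseudo-count.
#' @param seed integer seed for the Gibbs sampler.
#' @return list of class `line_model_config`.
#' @export
line_model_config <- function(models = default_line_models(),
                              r_lkhood = 0, n_iter = 2000L, burn_in = 200L,
                              dirichlet_prior = 1, seed = 1L) {
  if (abs(r_lkhood) >= 1) .stopf("|r_lkhood| must be < 1")
  if (burn_in >= n_iter) .stopf("burn_in must be smaller than n_iter")
  stopifnot(length(models) >= 1, dirichlet_prior > 0)
  structure(list(models = models, r_lkhood = r_lkhood,
                 n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 dirichlet_prior = dirichlet_prior, seed = as.integer(seed)),
            class = "line_model_config")
}

#' Prior covariance of a line model
#'
#' `scale` is the prior standard deviation of the larger of the two effects:
#' for `|slope| <= 1`, `sd1 = scale` and `sd2 = |slope| * scale`; for
#' `|slope| > 1`, `sd2 = scale` and `sd1 = scale / |slope|`. The off-diagonal
#' is `sign(slope) * cor * sd1 * sd2`. Slope 0 degenerates to
#' `diag(scale^2, 0)`; slope `Inf` to `diag(0, scale^2)`. This normalization
#' makes the model set symmetric under exchanging the two axes with slopes
#' mapped to their reciprocals (SHARED0.5 and SHARED2 are exact mirror
#' images). Always positive semidefinite.
#'
#' @param spec a [line_model_spec()].
#' @return 2x2 covariance matrix.
#' @export
prior_covariance <- function(spec) {
  stopifnot(inherits(spec, "line_model_spec"))
  s <- spec$scale
  if (is.infinite(spec$slope)) {
    return(matrix(c(0, 0, 0, s^2), 2, 2))
  }
  if (spec$slope == 0) {
    return(matrix(c(s^2, 0, 0, 0), 2, 2))
  }
  a <- abs(spec$slope)
  sd1 <- if (a <= 1) s else s / a
  sd2 <- if (a <= 1) a * s else s
  off <- sign(spec$slope) * spec$cor * sd1 * sd2
  matrix(c(sd1^2, off, off, sd2^2), 2, 2)
}

# log density of a zero-mean bivariate normal at rows of B (n x 2) with
# covariance Sigma (2 x 2).
#' @keywords internal
#' @noRd
.bvn_logdens <- function(b1, b2, Sigma) {
  det <- Sigma[1, 1] * Sigma[2, 2] - Sigma[1, 2]^2
  if (det <= 0) .stopf("singular total covariance in line-model likelihood")
  # inverse of 2x2
  i11 <- Sigma[2, 2] / det; i22 <- Sigma[1, 1] / det
  i12 <- -Sigma[1, 2] / det
  q <- i11 * b1^2 + 2 * i12 * b1 * b2 + i22 * b2^2
  -log(2 * pi) - 0.5 * log(det) - 0.5 * q
}

#' Marginal log-likelihood of an effect pair under a line model
#'
#' The hierarchical model `beta ~ N(0, Sigma_prior(spec))`,
#' `b ~ N(beta, Sigma_obs)` marginalizes to a zero-mean bivariate normal
#' with covariance `Sigma_prior + Sigma_obs`, where
#' `Sigma_obs = [[se1^2, r se1 se2], [r se1 se2, se2^2]]` and `r` is the
#' correlation between the two effect estimators.
#'
#' @param b length-2 observed effect pair (or n x 2 matrix).
#' @param se length-2 standard errors (or n x 2 matrix), > 0.
#' @param spec a [line_model_spec()].
#' @param r_lkhood estimator correlation.
#' @return log density (vector if matrices given).
#' @export
marginal_loglik <- function(b, se, spec, r_lkhood = 0) {
  b <- rbind(b); se <- rbind(se)
  if (any(se <= 0)) .stopf("standard errors must be positive")
  Sp <- prior_covariance(spec)
  out <- vapply(seq_len(nrow(b)), function(i) {
    So <- matrix(c(se[i, 1]^2, r_lkhood * se[i, 1] * se[i, 2],
                   r_lkhood * se[i, 1] * se[i, 2], se[i, 2]^2), 2, 2)
    .bvn_logdens(b[i, 1], b[i, 2], Sp + So)
  }, 0)
  unname(out)
}

# n x K matrix of marginal log-likelihoods for an effect-pair table
#' @keywords internal
#' @noRd
.loglik_matrix <- function(pairs, models, r_lkhood) {
  ll <- vapply(models, function(spec) {
    marginal_loglik(cbind(pairs$b1, pairs$b2), cbind(pairs$se1, pairs$se2),
                    spec, r_lkhood)
  }, numeric(nrow(pairs)))
  ll <- matrix(ll, nrow = nrow(pairs),
               dimnames = list(pairs$gene_id,
                               vapply(models, `[[`, "", "name")))
  ll
}

#' Posterior model probabilities at fixed mixture proportions
#'
#' `PP_gk` is proportional to `pi_k * exp(marginal_loglik(b_g, se_g, model
#' k))`, row-normalized with log-sum-exp stabilization.
#'
#' @param pairs data.frame `gene_id, b1, se1, b2, se2`.
#' @param config a [line_model_config()].
#' @param proportions mixture proportions on the simplex (one per model).
#' @return n x K matrix of posterior probabilities; rows sum to 1.
#' @export
posterior_probs <- function(pairs, config = line_model_config(),
                            proportions = NULL) {
  stopifnot(inherits(config, "line_model_config"))
  K <- length(config$models)
  if (is.null(proportions)) proportions <- rep(1 / K, K)
  .check_prob_vector(proportions, "proportions", tol = 1e-9)
  ll <- .loglik_matrix(pairs, config$models, config$r_lkhood)
  .pp_from_ll(ll, proportions)
}

#' @keywords internal
#' @noRd
.pp_from_ll <- function(ll, proportions) {
  lp <- sweep(ll, 2, log(proportions), `+`)
  pp <- exp(lp - .row_logsumexp(lp))
  pp / rowSums(pp)
}

#' Gibbs estimation of line-model mixture proportions
#'
#' Alternates (i) sampling a model assignment for every gene from its current
#' posterior probabilities and (ii) sampling the mixture proportions from a
#' Dirichlet(prior + assignment counts), for `n_iter` sweeps. Reports the
#' posterior mean and SD of the proportions over post-burn-in sweeps, and a
#' Rao-Blackwellized posterior-probability matrix (the post-burn-in average
#' of the per-sweep membership probabilities). Reproducible at a fixed seed.
#'
#' @param pairs data.frame `gene_id, b1, se1, b2, se2` (0 rows allowed: the
#'   prior is returned).
#' @param config a [line_model_config()].
#' @return object of class `line_model_result`: `proportions`,
#'   `proportions_se`, `pp` (n x K matrix), `models`, `config`.
#' @export
gibbs_proportions <- function(pairs, config = line_model_config()) {
  stopifnot(inherits(config, "line_model_config"))
  K <- length(config$models)
  model_names <- vapply(config$models, `[[`, "", "name")
  alpha <- rep(config$dirichlet_prior, K)
  n <- nrow(pairs)
  if (n == 0) {
    a0 <- sum(alpha)
    pm <- alpha / a0
    psd <- sqrt(alpha * (a0 - alpha) / (a0^2 * (a0 + 1)))
    return(structure(list(
      proportions = stats::setNames(pm, model_names),
      proportions_se = stats::setNames(psd, model_names),
      pp = matrix(numeric(0), 0, K, dimnames = list(NULL, model_names)),
      models = config$models, config = config),
      class = "line_model_result"))
  }
  ll <- .loglik_matrix(pairs, config$models, config$r_lkhood)
  set.seed(config$seed)
  pi_cur <- .rdirichlet1(alpha)
  cum_mat <- upper.tri(matrix(0, K, K), diag = TRUE) * 1  # for row cumsums
  keep <- config$n_iter - config$burn_in
  pi_sum <- numeric(K); pi_sq <- numeric(K)
  pp_sum <- matrix(0, n, K)
  for (it in seq_len(config$n_iter)) {
    pp <- .pp_from_ll(ll, pi_cur)
    cp <- pp %*% cum_mat                      # row-wise cumulative sums
    z <- 1L + rowSums(stats::runif(n) > cp[, -K, drop = FALSE])
    counts <- tabulate(z, nbins = K)
    pi_cur <- .rdirichlet1(alpha + counts)
    if (it > config$burn_in) {
      pi_sum <- pi_sum + pi_cur
      pi_sq <- pi_sq + pi_cur^2
      pp_sum <- pp_sum + pp
    }
  }
  pm <- pi_sum / keep
  psd <- sqrt(pmax(0, pi_sq / keep - pm^2) * keep / max(1, keep - 1))
  pp_mean <- pp_sum / keep
  pp_mean <- pp_mean / rowSums(pp_mean)
  dimnames(pp_mean) <- list(pairs$gene_id, model_names)
  structure(list(proportions = stats::setNames(pm, model_names),
                 proportions_se = stats::setNames(psd, model_names),
                 pp = pp_mean, models = config$models, config = config),
            class = "line_model_result")
}

#' Classify genes from posterior probabilities
#'
#' A gene is `shared` if the sum of the three shared-model probabilities
#' (SHARED0.5 + SHARED1 + SHARED2) exceeds the threshold; its shared
#' sub-label is whichever single shared model itself exceeds the threshold,
#' else `unspecified`. `prenatal-specific`, `adult-specific` and `opposite`
#' require the corresponding single model probability to exceed the
#' threshold. Anything else is `unclassified`.
#'
#' @param pp posterior-probability matrix with columns named after the six
#'   default models (rows sum to 1).
#' @param threshold posterior-probability threshold (default 0.8).
#' @return data.frame `gene_id, category, shared_sublabel`.
#' @export
classify_genes <- function(pp, threshold = 0.8) {
  need <- c("PRENATAL", "SHARED0.5", "SHARED1", "SHARED2", "ADULT",
            "OPPOSITE")
  if (!all(need %in% colnames(pp))) {
    .stopf("pp must have columns: %s", paste(need, collapse = ", "))
  }
  if (nrow(pp) > 0 && any(abs(rowSums(pp) - 1) > 1e-6)) {
    .stopf("malformed posterior-probability rows (do not sum to 1)")
  }
  shared_sum <- pp[, "SHARED0.5"] + pp[, "SHARED1"] + pp[, "SHARED2"]
  category <- rep("unclassified", nrow(pp))
  category[shared_sum > threshold] <- "shared"
  category[pp[, "PRENATAL"] > threshold] <- "prenatal-specific"
  category[pp[, "ADULT"] > threshold] <- "adult-specific"
  category[pp[, "OPPOSITE"] > threshold] <- "opposite"
  sub <- rep(NA_character_, nrow(pp))
  is_sh <- category == "shared"
  sub[is_sh] <- "unspecified"
  for (m in c("SHARED0.5", "SHARED1", "SHARED2")) {
    sub[is_sh & pp[, m] > threshold] <- m
  }
  data.frame(gene_id = if (is.null(rownames(pp))) seq_len(nrow(pp)) else
    rownames(pp),
    category = category, shared_sublabel = sub,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Prior scale from the discovery effect sizes
#'
#' The 95th percentile (linear-interpolation convention) of the absolute
#' logFC of the discovery (prenatal) sex-DE genes, divided by 2.
#'
#' @param logfc vector of logFC values.
#' @return scalar scale.
#' @export
compute_scale <- function(logfc) {
  if (length(logfc) == 0) .stopf("empty logFC vector")
  unname(stats::quantile(abs(logfc), probs = 0.95, type = 7) / 2)
}

#' Estimator correlation for overlapping-individual dataset pairs
#'
#' Pearson correlation of the logFC of all genes that are not strongly
#' sex-DE (p > 0.10) in both datasets; used as `r_lkhood` when the two
#' datasets share individuals.
#'
#' @param logfc1,p1 effects and p values in dataset 1.
#' @param logfc2,p2 effects and p values in dataset 2 (same gene order).
#' @return Pearson correlation.
#' @export
estimate_r_lkhood <- function(logfc1, p1, logfc2, p2) {
  stopifnot(length(logfc1) == length(p1), length(logfc1) == length(logfc2),
            length(logfc2) == length(p2))
  keep <- p1 > 0.10 & p2 > 0.10
  if (sum(keep) < 3) {
    .stopf("fewer than 3 genes with p > 0.10 in both datasets")
  }
  stats::cor(logfc1[keep], logfc2[keep])
}
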