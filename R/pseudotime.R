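#' Select the most highly variable genes
#'
#' Ranks genes by the variance of their log2 expression and returns the top
#' `k` gene ids; ties are broken by gene-id lexicographic order. The returned
#' set should be excluded from pseudotime-related differential-expression
#' reporting (see [fit_gene_models()]), because these genes define the
#' trajectory itself.
#'
#' @param norm a `normalized_matrix` (from [log_cpm()] / [normalize_counts()])
#'   or a genes x samples matrix of log2 expression.
#' @param k number of genes to select.
#' @return character vector of gene ids, length `k`.
#' @export
select_variable_genes <- function(norm, k) {
  y <- if (inherits(norm, "normalized_matrix")) norm$logcpm else norm
  if (k <= 0) .stopf("k must be positive")
  if (k > nrow(y)) .stopf("k (%d) exceeds the number of genes (%d)",
                          k, nrow(y))
  v <- apply(y, 1, stats::var)
  ord <- order(-v, rownames(y))
  rownames(y)[ord[seq_len(k)]]
}

#' Fit a covariate-adjusted latent pseudotime
#'
#' Fits the factor model
#' `y_gn = mu_g + c_g z_n + alpha_g x_n + beta_g x_n z_n + e_gn`,
#' where `z` is a per-sample latent pseudotime and `x` a binary covariate
#' (here sex, female = 1), by block coordinate descent on the penalized
#' least-squares objective `sum(e^2) + ridge * sum(c^2 + alpha^2 + beta^2) +
#' sum(z^2)` (the `z` penalty is a unit-normal prior). Given `z`, per-gene
#' coefficients are ridge least squares; given the coefficients, each `z_n`
#' has a closed-form update. Both steps minimize the same objective, so it is
#' non-increasing across sweeps. `z` is initialized from the first principal
#' component of the gene-centered matrix and standardized (mean 0, variance
#' 1) in the returned fit.
#'
#' @param y genes x samples matrix of log2 expression (the selected variable
#'   genes), or a `normalized_matrix`.
#' @param sex per-sample binary covariate (0/1 numeric, or a vector with
#'   values `"female"`/`"male"`; female is coded 1).
#' @param tol relative objective-change convergence tolerance.
#' @param max_iter maximum number of sweeps.
#' @param ridge ridge penalty on the loadings.
#' @return object of class `trajectory_fit`: `z` (standardized pseudotime,
#'   named by sample), `mu`, `loading` (c), `sex_effect` (alpha),
#'   `interaction` (beta), `objective` trace, `converged`, `genes`.
#' @export
fit_trajectory <- function(y, sex, tol = 1e-6, max_iter = 2000L,
                           ridge = 1e-6) {
  if (inherits(y, "normalized_matrix")) y <- y$logcpm
  x <- .as_sex01(sex)
  n <- ncol(y)
  if (length(x) != n) .stopf("sex must have one entry per sample")
  if (n < 3) .stopf("need at least 3 samples")

  # init: first principal component of the covariate-adjusted matrix (per-gene
  # sex-group means removed), so the latent axis starts in the expression
  # variation not attributable to sex
  yc <- y - rowMeans(y)
  for (lev in unique(x)) {
    idx <- x == lev
    yc[, idx] <- yc[, idx, drop = FALSE] -
      rowMeans(yc[, idx, drop = FALSE])
  }
  sv <- svd(yc, nu = 0, nv = 1)
  z <- sv$v[, 1] * sv$d[1] / sqrt(max(1, nrow(y)))
  # deterministic init sign: largest-|z| sample positive
  if (z[which.max(abs(z))] < 0) z <- -z

  obj <- numeric(0)
  converged <- FALSE
  coefs <- NULL
  pen <- diag(c(0, ridge, ridge, ridge))
  for (it in seq_len(max_iter)) {
    # (a) per-gene ridge least squares given z
    D <- cbind(1, z, x, x * z)
    M <- crossprod(D) + pen
    coefs <- solve(M, crossprod(D, t(y)))  # 4 x G
    mu <- coefs[1, ]; cg <- coefs[2, ]; ag <- coefs[3, ]; bg <- coefs[4, ]
    # (b) per-sample posterior mean of z under unit-normal prior
    A <- outer(cg, rep(1, n)) + outer(bg, x)      # genes x samples slopes
    R <- y - mu - outer(ag, x)                    # residual w.r.t. z term
    z <- colSums(A * R) / (colSums(A^2) + 1)
    resid <- R - A * matrix(z, nrow(y), n, byrow = TRUE)
    j <- sum(resid^2) + ridge * sum(cg^2 + ag^2 + bg^2) + sum(z^2)
    obj <- c(obj, j)
    if (it > 1 && abs(obj[it - 1] - j) <= tol * abs(obj[it - 1])) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("trajectory fit did not converge in ", max_iter,
            " sweeps; returning last iterate")
  }
  zs <- (z - mean(z)) / stats::sd(z)
  structure(list(z = stats::setNames(as.numeric(zs), colnames(y)),
                 mu = mu, loading = cg, sex_effect = ag, interaction = bg,
                 objective = obj, converged = converged,
                 genes = rownames(y)),
            class = "trajectory_fit")
}

#' @keywords internal
#' @noRd
.as_sex01 <- function(sex) {
  if (is.character(sex) || is.factor(sex)) {
    sex <- as.character(sex)
    bad <- setdiff(unique(sex), c("female", "male"))
    if (length(bad)) .stopf("unknown sex label(s): %s",
                            paste(bad, collapse = ", "))
    as.numeric(sex == "female")
  } else {
    as.numeric(sex)
  }
}

#' Orient a pseudotime fit
#'
#' Fixes the sign of the latent pseudotime. With an ordinal `anchor` (e.g.
#' reported developmental stages), `z` is negated when Kendall's tau between
#' `z` and the anchor is negative, so the returned correlation is
#' non-negative. Without an anchor, the sign is fixed by making the loading
#' of the largest-|loading| gene positive. Idempotent.
#'
#' @param fit a `trajectory_fit`.
#' @param anchor optional per-sample ordinal (>= 2 distinct values).
#' @return the fit with `z` (and loadings) possibly negated.
#' @export
orient_pseudotime <- function(fit, anchor = NULL) {
  stopifnot(inherits(fit, "trajectory_fit"))
  flip <- FALSE
  if (!is.null(anchor)) {
    if (length(unique(anchor)) < 2) {
      warning("constant anchor; falling back to the loading sign rule")
      anchor <- NULL
    }
  }
  if (!is.null(anchor)) {
    tau <- stats::cor(fit$z, as.numeric(anchor), method = "kendall")
    flip <- is.finite(tau) && tau < 0
  } else {
    i <- which.max(abs(fit$loading))
    flip <- fit$loading[i] < 0
  }
  if (flip) {
    fit$z <- -fit$z
    fit$loading <- -fit$loading
    fit$interaction <- -fit$interaction
  }
  fit
}

#' Kendall correlation between pseudotime and ordinal stages
#'
#' Tau-b with tie handling and the normal-approximation p value, as used to
#' check the inferred trajectory against reported developmental stages
#' (converted to a continuous variable).
#'
#' @param z per-sample pseudotime.
#' @param stages per-sample ordinal (numeric or ordered factor).
#' @return list `tau`, `p.value`.
#' @export
stage_correlation <- function(z, stages) {
  stages <- as.numeric(if (is.factor(stages)) as.integer(stages) else stages)
  if (length(unique(stages)) < 2) .stopf("stages are all tied")
  ct <- suppressWarnings(
    stats::cor.test(z, stages, method = "kendall", exact = FALSE))
  list(tau = unname(ct$estimate), p.value = ct$p.value)
}

#' Sensitivity of pseudotime-DE to the sex covariate
#'
#' Refits the trajectory with sex labels permuted across individuals (not
#' samples), reruns the pseudotime differential-expression analysis, and
#' reports, for each permutation, the percentage overlap of significant
#' pseudotime-DE genes with the unpermuted run (relative to the unpermuted
#' significant set) and the Pearson correlation of the pseudotime effect
#' sizes. Each permuted fit is oriented against the unpermuted pseudotime so
#' that sign flips of the latent axis do not masquerade as instability.
#'
#' @param norm `normalized_matrix` or genes x samples log2-expression matrix.
#' @param sex per-sample sex labels.
#' @param individual_id per-sample individual ids.
#' @param n_genes number of variable genes for the trajectory.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @param q_threshold significance threshold on the pseudotime q value.
#' @param ... passed to [fit_trajectory()].
#' @return data.frame with one row per permutation: `overlap_pct`,
#'   `effect_cor`.
#' @export
permuted_sex_sensitivity <- function(norm, sex, individual_id,
                                     n_genes = 500, n_perm = 10, seed = 1,
                                     q_threshold = 0.01, ...) {
  y <- if (inherits(norm, "normalized_matrix")) norm$logcpm else norm
  if (n_perm < 1) {
    return(data.frame(overlap_pct = numeric(0), effect_cor = numeric(0)))
  }
  x <- .as_sex01(sex)
  traj_genes <- select_variable_genes(y, min(n_genes, nrow(y) - 1L))

  run_once <- function(xperm) {
    fit <- fit_trajectory(y[traj_genes, , drop = FALSE], xperm, ...)
    de <- fit_gene_models(y, sex = xperm, pseudotime = fit$z,
                          individual_id = individual_id,
                          exclude_from_pseudotime = traj_genes)
    de$pseudotime
  }
  base <- run_once(x)
  base_sig <- base$gene_id[base$significant]

  ind <- unique(individual_id)
  x_ind <- x[match(ind, individual_id)]
  set.seed(seed)
  out <- lapply(seq_len(n_perm), function(b) {
    perm <- sample(x_ind)
    xp <- perm[match(individual_id, ind)]
    tab <- run_once(xp)
    # align effect signs through the latent axis orientation: correlate as-is
    # and flip if the trajectory came out mirrored
    r <- stats::cor(base$logFC, tab$logFC)
    if (is.finite(r) && r < 0) {
      tab$logFC <- -tab$logFC
      r <- -r
    }
    sig <- tab$gene_id[tab$significant]
    ov <- if (length(base_sig)) {
      100 * length(intersect(base_sig, sig)) / length(base_sig)
    } else {
      NA_real_
    }
    c(overlap_pct = ov, effect_cor = r)
  })
  as.data.frame(do.call(rbind, out))
}
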