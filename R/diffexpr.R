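#' Per-gene differential expression for sex, pseudotime and their interaction
#'
#' Fits, for every gene, the linear model
#' `expression ~ sex + pseudotime + sex:pseudotime (+ extra covariates)` by
#' least squares, with repeated samples per individual handled through
#' cluster-robust (CR1) covariance clustered on `individual_id`. The t
#' statistics use `df = #clusters - #parameters`. Three tables are extracted
#' (sex-DE, pseudotime-DE, interaction-DE); the pseudotime table excludes the
#' genes used to infer the trajectory, whose expression defines pseudotime
#' and would be reported circularly. The sign convention is positive =
#' female-biased (sex is coded female = 1) / increasing with pseudotime.
#' q values (Storey) are computed within each term's reported gene set.
#'
#' @param norm `normalized_matrix` or genes x samples log2-expression matrix.
#' @param sex per-sample sex (0/1 or `"female"`/`"male"`).
#' @param pseudotime per-sample numeric covariate.
#' @param individual_id per-sample individual ids (clusters).
#' @param extra_covariates optional numeric matrix/data.frame of additional
#'   fixed covariates (one row per sample).
#' @param exclude_from_pseudotime gene ids excluded from the pseudotime
#'   table (typically the trajectory-selection genes).
#' @param q_threshold significance threshold (default 0.01).
#' @return object of class `de_fit`: data.frames `sex`, `pseudotime`,
#'   `interaction` (gene_id, logFC, SE, t, p, qvalue, significant), plus
#'   `df` (residual degrees of freedom), `n_clusters` and `model` descriptor.
#' @export
fit_gene_models <- function(norm, sex, pseudotime, individual_id,
                            extra_covariates = NULL,
                            exclude_from_pseudotime = NULL,
                            q_threshold = 0.01) {
  y <- if (inherits(norm, "normalized_matrix")) norm$logcpm else norm
  x <- .as_sex01(sex)
  n <- ncol(y)
  stopifnot(length(x) == n, length(pseudotime) == n,
            length(individual_id) == n)
  X <- cbind(intercept = 1, sex = x, pseudotime = as.numeric(pseudotime),
             sex_pseudotime = x * as.numeric(pseudotime))
  if (!is.null(extra_covariates)) {
    ec <- as.matrix(extra_covariates)
    if (is.null(colnames(ec))) colnames(ec) <- paste0("cov", seq_len(ncol(ec)))
    X <- cbind(X, ec)
  }
  p <- ncol(X)
  qrx <- qr(X)
  if (qrx$rank < p) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1):p]]
    .stopf("design matrix is rank deficient; collinear column(s): %s",
           paste(bad, collapse = ", "))
  }
  clusters <- unique(individual_id)
  G <- length(clusters)
  if (G <= p) {
    .stopf("number of clusters (%d) must exceed number of parameters (%d)",
           G, p)
  }
  if (n < p + 2) .stopf("need at least %d samples", p + 2)

  A <- chol2inv(chol(crossprod(X)))          # (X'X)^-1, p x p
  Yt <- t(y)                                 # n x G_genes
  coef <- A %*% crossprod(X, Yt)             # p x G_genes
  rownames(coef) <- colnames(X)
  E <- Yt - X %*% coef                       # n x G_genes

  # CR1 cluster-robust variance: c * sum_c (A X_c' e_c)(...)' diagonals
  V <- matrix(0, p, ncol(coef))
  for (cl in clusters) {
    idx <- which(individual_id == cl)
    S <- crossprod(X[idx, , drop = FALSE], E[idx, , drop = FALSE])
    TT <- A %*% S
    V <- V + TT^2
  }
  cr1 <- (G / (G - 1)) * ((n - 1) / (n - p))
  SE <- sqrt(cr1 * V)
  rownames(SE) <- colnames(X)
  df <- G - p
  tstat <- coef / SE
  pval <- 2 * stats::pt(-abs(tstat), df = df)

  term_table <- function(term, keep = NULL) {
    gid <- rownames(y)
    tab <- data.frame(gene_id = gid, logFC = coef[term, ], SE = SE[term, ],
                      t = tstat[term, ], p = pval[term, ],
                      stringsAsFactors = FALSE, row.names = NULL)
    if (!is.null(keep)) tab <- tab[tab$gene_id %in% keep, , drop = FALSE]
    qv <- storey_qvalues(tab$p)
    tab$qvalue <- qv$qvalues
    tab$significant <- tab$qvalue < q_threshold
    rownames(tab) <- NULL
    tab
  }
  pt_universe <- setdiff(rownames(y), exclude_from_pseudotime)
  structure(list(
    sex = term_table("sex"),
    pseudotime = term_table("pseudotime", keep = pt_universe),
    interaction = term_table("sex_pseudotime"),
    df = df, n_clusters = G,
    model = paste("expression ~", paste(colnames(X)[-1], collapse = " + "),
                  "| cluster(individual)")),
    class = "de_fit")
}

#' Storey q-values
#'
#' Estimates the null proportion pi0 and converts p values into q values.
#' With a lambda grid (default 0.05..0.95 by 0.05), pi0 is the smoother
#' estimate: a df-3 smoothing spline through `pi0(lambda) =
#' #\{p > lambda\} / (m (1 - lambda))` evaluated at the largest lambda,
#' capped into (0, 1]. With a single fixed lambda, the plug-in estimate is
#' used directly. `q_(i) = pi0 * m * p_(i) / i` with cumulative-minimum
#' enforcement from the largest p value down.
#'
#' @param p vector of p values in \[0, 1\].
#' @param lambda lambda grid or a single fixed value.
#' @return list of class `qvalue_result`: `pi0`, `qvalues` (same order as
#'   `p`), `lambda`.
#' @export
storey_qvalues <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  if (length(p) == 0) .stopf("empty p-value vector")
  if (any(p < 0 | p > 1 | is.na(p))) .stopf("p values must lie in [0, 1]")
  m <- length(p)
  if (length(lambda) == 1) {
    pi0 <- sum(p > lambda) / (m * (1 - lambda))
  } else {
    pi0l <- vapply(lambda, function(l) sum(p > l) / (m * (1 - l)), 0)
    fit <- stats::smooth.spline(lambda, pi0l, df = 3)
    pi0 <- stats::predict(fit, x = max(lambda))$y
  }
  pi0 <- min(max(pi0, 1 / m), 1)
  o <- order(p, decreasing = TRUE)
  q <- pi0 * m * p[o] / rank(p, ties.method = "max")[o]
  q <- pmin(cummin(q), 1)
  qvalues <- numeric(m)
  qvalues[o] <- q
  structure(list(pi0 = pi0, qvalues = qvalues, lambda = lambda),
            class = "qvalue_result")
}

#' Replication rate pi1
#'
#' Fraction of true positives among discovery-significant genes estimated
#' from their p values in the replication dataset:
#' `pi1 = 1 - pi0(lambda = 0.5) = 1 - #\{p > 0.5\} / (0.5 m)`, clipped to
#' \[0, 1\].
#'
#' @param p_replication p values, in the replication dataset, of the genes
#'   significant in the discovery dataset.
#' @return pi1 (scalar in \[0, 1\]).
#' @export
pi1_replication <- function(p_replication) {
  if (length(p_replication) == 0) .stopf("empty replication p-value vector")
  pi0 <- sum(p_replication > 0.5) / (0.5 * length(p_replication))
  min(max(1 - pi0, 0), 1)
}

#' Exact binomial test for direction bias
#'
#' Two-sided exact binomial test of the fraction of female-biased genes
#' against 0.5 (small-p-value definition: sum of outcome probabilities not
#' exceeding that of the observed count).
#'
#' @param n_female_biased number of female-biased genes.
#' @param n_total total number of sex-DE genes.
#' @return two-sided p value.
#' @export
sign_bias_test <- function(n_female_biased, n_total) {
  if (n_total <= 0) .stopf("n_total must be positive")
  stopifnot(n_female_biased >= 0, n_female_biased <= n_total)
  stats::binom.test(n_female_biased, n_total, p = 0.5)$p.value
}
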