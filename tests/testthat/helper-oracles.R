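# Independent re-implementations used as oracles. These deliberately use
# different code paths from the package (naive loops, closed forms,
# enumeration) so that agreement is informative.

# Naive weighted trimmed-mean-of-M-values, straight from the published
# algorithm: M/A values on depth-scaled counts, 30%/5% rank trimming,
# inverse-asymptotic-variance weighting, geometric-mean-1 rescaling.
naive_tmm <- function(counts, ref_col) {
  lib <- colSums(counts)
  f <- vapply(seq_len(ncol(counts)), function(j) {
    obs <- counts[, j]; ref <- counts[, ref_col]
    nO <- lib[j]; nR <- lib[ref_col]
    logR <- log2((obs / nO) / (ref / nR))
    absE <- (log2(obs / nO) + log2(ref / nR)) / 2
    v <- (nO - obs) / (nO * obs) + (nR - ref) / (nR * ref)
    fin <- is.finite(logR) & is.finite(absE)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * 0.3) + 1; hiL <- n + 1 - loL
    loS <- floor(n * 0.05) + 1; hiS <- n + 1 - loS
    keep <- rank(logR) >= loL & rank(logR) <= hiL &
      rank(absE) >= loS & rank(absE) <= hiS
    2^(sum(logR[keep] / v[keep]) / sum(1 / v[keep]))
  }, 0)
  f / exp(mean(log(f)))
}

# the upper-quartile reference rule used by the package
tmm_reference_col <- function(counts) {
  uq <- apply(counts, 2, stats::quantile, probs = 0.75) / colSums(counts)
  which.min(abs(uq - mean(uq)))
}

# O(n^2) concordant/discordant pair counting for Kendall tau-b with ties
naive_tau_b <- function(x, y) {
  n <- length(x)
  C <- 0; D <- 0; tx <- 0; ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sx <- sign(x[j] - x[i]); sy <- sign(y[j] - y[i])
    if (sx == 0 && sy == 0) next
    if (sx == 0) tx <- tx + 1
    else if (sy == 0) ty <- ty + 1
    else if (sx == sy) C <- C + 1
    else D <- D + 1
  }
  (C - D) / sqrt((C + D + tx) * (C + D + ty))
}

# exact upper-tail hypergeometric by enumeration of all query draws
enum_hyper_p <- function(n_query, n_annotation, n_universe, observed) {
  total <- 0
  for (k in 0:n_query) {
    if (k >= observed) {
      total <- total + choose(n_annotation, k) *
        choose(n_universe - n_annotation, n_query - k)
    }
  }
  total / choose(n_universe, n_query)
}

# posterior mean mixture proportions by exhaustive enumeration over all
# model-assignment vectors, weighted by likelihood x Dirichlet-multinomial
enum_proportions <- function(pairs, models, alpha, r_lkhood = 0) {
  n <- nrow(pairs); K <- length(models)
  ll <- vapply(models, function(m) {
    marginal_loglik(cbind(pairs$b1, pairs$b2), cbind(pairs$se1, pairs$se2),
                    m, r_lkhood)
  }, numeric(n))
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  logw <- rowSums(matrix(ll[cbind(rep(seq_len(n), each = nrow(grid)),
                                  as.vector(grid))], nrow = nrow(grid)))
  cnt <- t(apply(grid, 1, tabulate, nbins = K))
  logw <- logw + rowSums(lgamma(t(t(cnt) + alpha)))
  w <- exp(logw - max(logw)); w <- w / sum(w)
  colSums(w * t(t(cnt) + alpha)) / (sum(alpha) + n)
}

# direct bivariate normal density (zero mean), for integration oracles
mvn_dens2 <- function(x1, x2, S) {
  det <- S[1, 1] * S[2, 2] - S[1, 2]^2
  i11 <- S[2, 2] / det; i22 <- S[1, 1] / det; i12 <- -S[1, 2] / det
  exp(-0.5 * (i11 * x1^2 + 2 * i12 * x1 * x2 + i22 * x2^2)) /
    (2 * pi * sqrt(det))
}

# small deterministic count fixture with marker genes, for preprocess tests
toy_marker_counts <- function() {
  counts <- rbind(
    geneA = c(100, 200, 150, 120),
    geneB = c(50, 80, 60, 70),
    XIST_like = c(9000, 300, 9000, 100),
    chrY1 = c(50, 6000, 4500, 9000),
    chrY2 = c(50, 6001, 4501, 1))
  colnames(counts) <- paste0("s", 1:4)
  genes <- data.frame(
    gene_id = rownames(counts),
    is_xist = rownames(counts) == "XIST_like",
    is_chry_marker = rownames(counts) %in% c("chrY1", "chrY2"),
    stringsAsFactors = FALSE)
  list(counts = counts, genes = genes)
}
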