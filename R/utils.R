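# Internal numerical helpers shared across modules.

#' @keywords internal
#' @noRd
.rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  # guard against all-zero draws for tiny alphas
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

# Row-wise log-sum-exp of a matrix.
#' @keywords internal
#' @noRd
.row_logsumexp <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

#' @keywords internal
#' @noRd
.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
#' @noRd
.check_prob_vector <- function(p, name, tol = 1e-12) {
  if (any(p < 0)) .stopf("%s must be non-negative", name)
  if (abs(sum(p) - 1) > tol) {
    .stopf("%s must sum to 1 (got %.15g)", name, sum(p))
  }
  invisible(p)
}
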