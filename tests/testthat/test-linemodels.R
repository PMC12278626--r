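test_that("prior covariance has the stated degenerate and full forms", {
  s <- 0.3
  expect_equal(prior_covariance(line_model_spec("PRENATAL", 0, s)),
               matrix(c(s^2, 0, 0, 0), 2, 2))
  expect_equal(prior_covariance(line_model_spec("ADULT", Inf, s)),
               matrix(c(0, 0, 0, s^2), 2, 2))
  expect_equal(prior_covariance(line_model_spec("SHARED1", 1, s, 0.995)),
               matrix(c(s^2, 0.995 * s^2, 0.995 * s^2, s^2), 2, 2))
  opp <- prior_covariance(line_model_spec("OPPOSITE", -1, s, 0.990))
  expect_equal(opp[1, 2], -0.990 * s^2)
  # scale is the sd of the larger effect: SHARED2 mirrors SHARED0.5
  sh2 <- prior_covariance(line_model_spec("SHARED2", 2, s, 0.995))
  sh05 <- prior_covariance(line_model_spec("SHARED0.5", 0.5, s, 0.995))
  expect_equal(sh2, sh05[2:1, 2:1])
  expect_equal(sh2[2, 2], s^2)
  expect_equal(sh2[1, 2], 0.995 * s * s / 2)
  expect_error(line_model_spec("bad", 1, cor = 1), "cor")
  # all six defaults are positive semidefinite
  for (m in default_line_models()) {
    expect_gte(min(eigen(prior_covariance(m))$values), -1e-12)
  }
})

test_that("marginal likelihood equals numerical integration of the hierarchical model", {
  b <- c(0.21, 0.12); se <- c(0.07, 0.05)
  # non-degenerate prior: 2-D grid integration over the latent effect pair
  spec <- line_model_spec("SHARED1", 1, scale = 0.2, cor = 0.995)
  Sp <- prior_covariance(spec)
  g <- seq(-1.2, 1.2, length.out = 601)
  bb <- expand.grid(b1 = g, b2 = g)
  pri <- mvn_dens2(bb$b1, bb$b2, Sp)
  lik <- dnorm(b[1], bb$b1, se[1]) * dnorm(b[2], bb$b2, se[2])
  num <- log(sum(pri * lik) * diff(g)[1]^2)
  expect_equal(marginal_loglik(b, se, spec), num, tolerance = 1e-4)
  # degenerate prior (slope 0): the effect lives on the first axis only
  spec0 <- line_model_spec("PRENATAL", 0, scale = 0.2)
  f <- function(t) dnorm(t, 0, 0.2) * dnorm(b[1], t, se[1]) *
    dnorm(b[2], 0, se[2])
  num0 <- log(integrate(f, -2, 2, rel.tol = 1e-10)$value)
  expect_equal(marginal_loglik(b, se, spec0), num0, tolerance = 1e-6)
})

test_that("model likelihood orderings follow the geometry", {
  models <- default_line_models(scale = 0.2)
  # at the origin, density ordering = ordering of 1/sqrt(det(total cov))
  se <- c(0.05, 0.05)
  ll0 <- vapply(models, function(m) marginal_loglik(c(0, 0), se, m), 0)
  dets <- vapply(models, function(m) {
    S <- prior_covariance(m) + diag(se^2)
    S[1, 1] * S[2, 2] - S[1, 2]^2
  }, 0)
  expect_equal(rank(ll0, ties.method = "average"),
               rank(1 / sqrt(dets), ties.method = "average"))
  # a strong prenatal-only effect prefers PRENATAL over SHARED1
  expect_gt(marginal_loglik(c(0.5, 0.01), se, models$PRENATAL),
            marginal_loglik(c(0.5, 0.01), se, models$SHARED1))
  # symmetric pairs prefer SHARED1 over OPPOSITE
  for (x in c(0.05, 0.2, 0.6)) {
    expect_gt(marginal_loglik(c(x, x), se, models$SHARED1),
              marginal_loglik(c(x, x), se, models$OPPOSITE))
  }
})

test_that("posterior probabilities normalize and match a direct computation", {
  set.seed(2)
  pairs <- data.frame(gene_id = paste0("g", 1:5),
                      b1 = rnorm(5, 0, 0.3), se1 = runif(5, 0.02, 0.1),
                      b2 = rnorm(5, 0, 0.3), se2 = runif(5, 0.02, 0.1))
  cfg <- line_model_config(models = default_line_models(scale = 0.25))
  pp <- posterior_probs(pairs, cfg)
  expect_equal(unname(rowSums(pp)), rep(1, 5), tolerance = 1e-9)
  # brute-force normalization without log-sum-exp
  ll <- vapply(cfg$models, function(m) {
    marginal_loglik(cbind(pairs$b1, pairs$b2), cbind(pairs$se1, pairs$se2),
                    m, 0)
  }, numeric(5))
  raw <- exp(ll) / 6
  expect_equal(unname(pp), unname(raw / rowSums(raw)), tolerance = 1e-9)
  # single model: probability one everywhere
  cfg1 <- line_model_config(models = default_line_models(scale = 0.25)[3])
  expect_true(all(posterior_probs(pairs, cfg1) == 1))
  # overwhelming likelihood pushes the posterior to 1
  strong <- data.frame(gene_id = "g", b1 = 0.6, se1 = 0.005, b2 = 0,
                       se2 = 0.005)
  expect_gt(posterior_probs(strong, cfg)[1, "PRENATAL"], 0.999)
})

test_that("axis swap with slope inversion leaves posteriors unchanged", {
  set.seed(6)
  pairs <- data.frame(gene_id = paste0("g", 1:40),
                      b1 = rnorm(40, 0, 0.3), se1 = runif(40, 0.02, 0.15),
                      b2 = rnorm(40, 0, 0.3), se2 = runif(40, 0.02, 0.15))
  cfg <- line_model_config(models = default_line_models(scale = 0.25))
  pp <- posterior_probs(pairs, cfg)
  swapped <- data.frame(gene_id = pairs$gene_id,
                        b1 = pairs$b2, se1 = pairs$se2,
                        b2 = pairs$b1, se2 = pairs$se1)
  pp_sw <- posterior_probs(swapped, cfg)
  # PRENATAL <-> ADULT, SHARED0.5 <-> SHARED2; SHARED1, OPPOSITE fixed
  map <- c(PRENATAL = "ADULT", "SHARED0.5" = "SHARED2", SHARED1 = "SHARED1",
           SHARED2 = "SHARED0.5", ADULT = "PRENATAL", OPPOSITE = "OPPOSITE")
  expect_equal(unname(pp), unname(pp_sw[, map[colnames(pp)]]),
               tolerance = 1e-6)
})

test_that("shrinking standard errors pins an on-line gene to its model", {
  models <- default_line_models(scale = 0.25)
  on_line <- list(PRENATAL = c(0.3, 0), "SHARED0.5" = c(0.3, 0.15),
                  SHARED1 = c(0.3, 0.3), SHARED2 = c(0.15, 0.3),
                  ADULT = c(0, 0.3), OPPOSITE = c(0.3, -0.3))
  cfg <- line_model_config(models = models)
  for (name in names(on_line)) {
    pairs <- data.frame(gene_id = "g", b1 = on_line[[name]][1], se1 = 1e-4,
                        b2 = on_line[[name]][2], se2 = 1e-4)
    pp <- posterior_probs(pairs, cfg)
    expect_equal(unname(colnames(pp)[which.max(pp)]), name)
  }
})

test_that("Gibbs proportions agree with exhaustive enumeration on few genes", {
  set.seed(3)
  n <- 6
  pairs <- data.frame(gene_id = paste0("g", 1:n),
                      b1 = rnorm(n, 0, 0.3), se1 = runif(n, 0.03, 0.1),
                      b2 = rnorm(n, 0, 0.3), se2 = runif(n, 0.03, 0.1))
  cfg <- line_model_config(models = default_line_models(scale = 0.2),
                           n_iter = 20000, burn_in = 1000, seed = 9)
  res <- gibbs_proportions(pairs, cfg)
  ref <- enum_proportions(pairs, cfg$models, rep(1, 6))
  # 0.015 is about 3 Monte-Carlo SEs for this chain length
  expect_lt(max(abs(res$proportions - ref)), 0.015)
  expect_equal(unname(rowSums(res$pp)), rep(1, n), tolerance = 1e-9)
  expect_equal(sum(res$proportions), 1, tolerance = 1e-9)
})

test_that("Gibbs sampler honors prior-only input, determinism and dominance", {
  cfg <- line_model_config(seed = 4)
  empty <- data.frame(gene_id = character(0), b1 = numeric(0),
                      se1 = numeric(0), b2 = numeric(0), se2 = numeric(0))
  res0 <- gibbs_proportions(empty, cfg)
  expect_equal(unname(res0$proportions), rep(1 / 6, 6))
  expect_error(line_model_config(n_iter = 100, burn_in = 100), "burn_in")
  # all genes on the equal-sharing line with small SEs
  cfgS <- simulation_config(
    n_genes = 1000,
    category_proportions = c(null = 0, PRENATAL = 0, "SHARED0.5" = 0,
                             SHARED1 = 1, SHARED2 = 0, ADULT = 0,
                             OPPOSITE = 0),
    se_range = c(0.01, 0.05), seed = 12)
  ep <- simulate_effect_pairs(cfgS)
  lmc <- line_model_config(models = default_line_models(scale = 0.35),
                           n_iter = 800, burn_in = 100, seed = 5)
  res <- gibbs_proportions(ep$pairs, lmc)
  expect_gte(res$proportions[["SHARED1"]], 0.9)
  res2 <- gibbs_proportions(ep$pairs, lmc)
  expect_identical(res$proportions, res2$proportions)
})

test_that("classification applies the shared-sum and single-model rules", {
  mk <- function(...) {
    row <- c(...)
    matrix(row / sum(row), 1,
           dimnames = list("g", c("PRENATAL", "SHARED0.5", "SHARED1",
                                  "SHARED2", "ADULT", "OPPOSITE")))
  }
  expect_equal(classify_genes(mk(0.95, 0.01, 0.01, 0.01, 0.01, 0.01))$category,
               "prenatal-specific")
  cl <- classify_genes(mk(0.05, 0.4, 0.3, 0.2, 0.03, 0.02))
  expect_equal(cl$category, "shared")
  expect_equal(cl$shared_sublabel, "unspecified")
  cl2 <- classify_genes(mk(0.05, 0.85, 0.04, 0.01, 0.03, 0.02))
  expect_equal(cl2$shared_sublabel, "SHARED0.5")
  expect_equal(classify_genes(mk(0.7, 0.1, 0.05, 0.05, 0.05, 0.05))$category,
               "unclassified")
  bad <- mk(0.95, 0.01, 0.01, 0.01, 0.01, 0.01)
  bad[1, 1] <- 0.5
  expect_error(classify_genes(bad), "malformed")
})

test_that("scale and estimator-correlation helpers follow their formulas", {
  expect_equal(compute_scale(rep(0.4, 50)), 0.2)
  expect_equal(compute_scale(rep(-0.4, 50)), 0.2)  # absolute values
  expect_equal(compute_scale(c(rep(0.1, 100), 0.6)), 0.05)
  # estimator correlation from weakly-associated genes only
  logfc1 <- c(1, 2, 3, 4, 5); logfc2 <- c(1, 2, 3, 4, -99)
  p1 <- c(0.5, 0.6, 0.7, 0.8, 0.9); p2 <- c(0.5, 0.6, 0.7, 0.8, 0.05)
  expect_equal(estimate_r_lkhood(logfc1, p1, logfc2, p2), 1)
  expect_error(estimate_r_lkhood(logfc1, rep(0.01, 5), logfc2, p2),
               "fewer than 3")
  set.seed(9)
  a <- rnorm(500); b <- rnorm(500)
  expect_lt(abs(estimate_r_lkhood(a, runif(500), b, runif(500))), 0.15)
})
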