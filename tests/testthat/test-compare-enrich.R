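# minimal DE-like table builder
de_table <- function(gene_id, logfc, p, q = p) {
  data.frame(gene_id = gene_id, logFC = logfc, SE = 0.1,
             t = logfc / 0.1, p = p, qvalue = q,
             significant = q < 0.01, stringsAsFactors = FALSE)
}

test_that("comparing a dataset with itself gives perfect consistency", {
  set.seed(1)
  g <- paste0("g", 1:300)
  lf <- rnorm(300, 0, 0.4)
  q <- c(rep(1e-4, 60), runif(240, 0.02, 1))
  de <- de_table(g, lf, p = q, q = q)
  rep <- compare_sexde(de, de)
  expect_equal(rep$consistency_pct, 100)
  expect_equal(rep$pearson_r, 1)
  expect_equal(rep$pi1_1to2, 1)
  expect_equal(rep$n_overlap, 60)
  expect_lt(rep$overlap_hypergeom_p, 1e-10)
})

test_that("independent null datasets show chance-level consistency", {
  set.seed(2)
  g <- paste0("g", 1:2000)
  de1 <- de_table(g, rnorm(2000), runif(2000),
                  q = c(rep(0.001, 400), rep(0.5, 1600)))
  de2 <- de_table(g, rnorm(2000), runif(2000), q = runif(2000))
  rep <- compare_sexde(de1, de2)
  expect_lt(abs(rep$consistency_pct - 50), 8)
  expect_lt(abs(rep$pearson_r), 0.15)
  expect_error(compare_sexde(de1, de_table("other", 1, 0.5)),
               "share no tested genes")
})

test_that("replication statistics increase with the shared fraction", {
  make_pair <- function(frac_shared, seed) {
    set.seed(seed)
    n <- 1500
    shared <- runif(n) < frac_shared
    beta <- rnorm(n, 0, 0.5)
    b1 <- beta + rnorm(n, 0, 0.05)
    b2 <- ifelse(shared, beta, 0) + rnorm(n, 0, 0.05)
    t2 <- b2 / 0.05
    p2 <- 2 * pnorm(-abs(t2))
    q1 <- ifelse(abs(b1 / 0.05) > 4, 1e-4, 0.5)
    list(de1 = de_table(paste0("g", 1:n), b1, p = 2 * pnorm(-abs(b1 / 0.05)),
                        q = q1),
         de2 = de_table(paste0("g", 1:n), b2, p2, q = p2))
  }
  stats <- lapply(c(0.1, 0.3, 0.6), function(f) {
    pr <- make_pair(f, seed = 31)
    rep <- compare_sexde(pr$de1, pr$de2)
    c(pi1 = rep$pi1_1to2, r = rep$pearson_r)
  })
  pi1s <- vapply(stats, `[[`, 0, "pi1")
  rs <- vapply(stats, `[[`, 0, "r")
  expect_true(all(diff(pi1s) > 0))
  expect_true(all(diff(rs) > 0))
})

test_that("hypergeometric enrichment matches closed forms and enumeration", {
  u <- paste0("g", 1:20)
  res <- hypergeom_enrichment(u[1:5], u[1:5], u)
  expect_equal(res$p.value, 1 / choose(20, 5))
  expect_equal(res$relative_enrichment, 5 / (5 * 5 / 20))
  # zero overlap has p = 1
  res0 <- hypergeom_enrichment(u[1:5], u[6:10], u)
  expect_equal(res0$p.value, 1)
  # exhaustive enumeration on a 6-gene universe
  u6 <- paste0("g", 1:6)
  res6 <- hypergeom_enrichment(u6[1:3], u6[c(1, 2, 4)], u6)
  expect_equal(res6$p.value, enum_hyper_p(3, 3, 6, res6$overlap))
  expect_error(hypergeom_enrichment(u6, u6, character(0)), "empty universe")
  expect_error(hypergeom_enrichment(c(u6, "new"), u6, u6), "subset")
})

test_that("matched permutation p is reproducible, bounded and exact for full annotation", {
  set.seed(4)
  universe <- paste0("g", 1:400)
  expr <- setNames(rgamma(400, 2), universe)
  query <- sample(universe, 40)
  ann <- sample(universe, 80)
  p1 <- matched_permutation_p(query, ann, universe, expr, B = 99, seed = 7)
  p2 <- matched_permutation_p(query, ann, universe, expr, B = 99, seed = 7)
  expect_identical(p1, p2)
  expect_gte(p1, 1 / 100)
  expect_lte(p1, 1)
  # annotation covering the universe ties every permutation
  expect_equal(matched_permutation_p(query, universe, universe, expr,
                                     B = 49, seed = 1), 1)
  # a query outside the binned universe cannot be matched
  expect_error(
    matched_permutation_p(c("absent", query), ann, universe, expr,
                          B = 9, seed = 1),
    "subset")
  # tied expression values collapse bins without breaking the matching
  expr_tied <- setNames(rep(c(0.1, 5), each = 200), universe)
  expect_lte(matched_permutation_p(query, ann, universe, expr_tied,
                                   B = 19, seed = 2), 1)
})

test_that("expression matching corrects a high-expression confounder", {
  # annotation concentrated in high-expression genes; query matched there too:
  # the naive hypergeometric overstates the surprise of a large overlap
  set.seed(8)
  universe <- paste0("g", 1:1000)
  expr <- setNames(sort(rgamma(1000, 2)), universe)
  ann <- universe[801:1000]                     # top-expression quintile
  query <- sample(universe[801:1000], 50)       # drawn from the same stratum
  naive <- hypergeom_enrichment(query, ann, universe)$p.value
  matched <- matched_permutation_p(query, ann, universe, expr, B = 199,
                                   seed = 3)
  expect_lt(naive, 0.001)   # naive test is fooled by the confounder
  expect_gt(matched, 0.2)   # matched background is not
})

test_that("the Bonferroni-and-permutation significance filter applies both gates", {
  f <- significance_filter(hyper_p = c(1e-5, 1e-3, 1e-5),
                           perm_p = c(0.01, 0.01, 0.2),
                           n_lists = 9, n_gene_groups = 8)
  expect_equal(f$threshold, 0.05 / 72)
  expect_equal(f$significant, c(TRUE, FALSE, FALSE))
  expect_equal(significance_filter(1, 1, 8, 4)$threshold, 1.5625e-3)
  # p just above the threshold is not flagged
  eps <- significance_filter(0.05 / 72 * 1.0001, 0.01, 9, 8)
  expect_false(eps$significant)
})

test_that("two-proportion chi-square reproduces known contingency results", {
  t1 <- two_proportion_test(31, 42, 22, 101)
  expect_equal(t1$p.value, 1.37e-8, tolerance = 5e-3)
  expect_equal(t1$statistic, 32.23, tolerance = 1e-3)
  t2 <- two_proportion_test(9, 42, 0, 101)
  expect_equal(t2$p.value, 9.52e-6, tolerance = 5e-3)
  expect_equal(two_proportion_test(5, 10, 5, 10)$p.value, 1)
  expect_error(two_proportion_test(0, 0, 1, 10), "positive")
})

test_that("XCI class table counts shared genes and tests class differences", {
  categories <- c(rep("shared", 31), rep("prenatal-specific", 11),
                  rep("shared", 22), rep("unclassified", 79))
  xci <- c(rep("escape", 42), rep("inactive", 101))
  res <- xci_category_table(categories, xci)
  tab <- res$table
  expect_equal(tab$n_shared[tab$class == "escape"], 31L)
  expect_equal(tab$n_total[tab$class == "escape"], 42L)
  expect_equal(tab$n_shared[tab$class == "inactive"], 22L)
  tst <- res$tests
  expect_equal(tst$p.value[tst$class1 == "escape" | tst$class2 == "escape"],
               1.37e-8, tolerance = 5e-3)
  # class with zero genes is dropped with a warning
  expect_warning(
    res2 <- xci_category_table(categories,
                               factor(xci, levels = c("escape", "inactive",
                                                      "variable"))),
    "0 genes")
  expect_setequal(res2$table$class, c("escape", "inactive"))
})
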