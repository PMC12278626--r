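#' Compare sex-DE results between two datasets
#'
#' Computes, on the shared tested gene universe: direction consistency (the
#' percentage of dataset-1-significant genes whose t statistic has the same
#' sign in dataset 2, with an exact binomial test against 0.5), the Pearson
#' correlation of logFC over dataset-1-significant genes, the replication
#' rate pi1 in both directions, direction-split overlap counts of the
#' significant sets, and a hypergeometric test of the overlap.
#'
#' @param de1,de2 sex-DE tables (data.frames with `gene_id, logFC, t, p,
#'   qvalue`), e.g. the `sex` component of a [fit_gene_models()] result.
#' @param q_threshold significance threshold (default 0.01).
#' @return list of class `comparison_report`.
#' @export
compare_sexde <- function(de1, de2, q_threshold = 0.01) {
  universe <- intersect(de1$gene_id, de2$gene_id)
  if (length(universe) == 0) .stopf("the two datasets share no tested genes")
  d1 <- de1[match(universe, de1$gene_id), ]
  d2 <- de2[match(universe, de2$gene_id), ]
  sig1 <- d1$qvalue < q_threshold
  sig2 <- d2$qvalue < q_threshold

  consistency <- NA_real_; consistency_p <- NA_real_
  r <- NA_real_; r_p <- NA_real_
  if (any(sig1)) {
    same <- sign(d1$t[sig1]) == sign(d2$t[sig1])
    consistency <- 100 * mean(same)
    consistency_p <- stats::binom.test(sum(same), length(same))$p.value
    if (sum(sig1) >= 3) {
      ct <- stats::cor.test(d1$logFC[sig1], d2$logFC[sig1])
      r <- unname(ct$estimate); r_p <- ct$p.value
    }
  }
  pi1_12 <- if (any(sig1)) pi1_replication(d2$p[sig1]) else NA_real_
  pi1_21 <- if (any(sig2)) pi1_replication(d1$p[sig2]) else NA_real_

  g1 <- universe[sig1]; g2 <- universe[sig2]
  both <- intersect(g1, g2)
  dir1 <- stats::setNames(ifelse(d1$logFC > 0, "female", "male"), universe)
  dir2 <- stats::setNames(ifelse(d2$logFC > 0, "female", "male"), universe)
  overlap_split <- table(direction1 = dir1[both], direction2 = dir2[both])
  overlap_test <- hypergeom_enrichment(g1, g2, universe)

  structure(list(
    n_universe = length(universe),
    n_sig1 = sum(sig1), n_sig2 = sum(sig2), n_overlap = length(both),
    n_sig1_only = length(setdiff(g1, g2)),
    n_sig2_only = length(setdiff(g2, g1)),
    overlap_direction_split = overlap_split,
    consistency_pct = consistency, consistency_p = consistency_p,
    pearson_r = r, pearson_p = r_p,
    pi1_1to2 = pi1_12, pi1_2to1 = pi1_21,
    overlap_hypergeom_p = overlap_test$p.value),
    class = "comparison_report")
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of the overlap between a query set and an
#' annotation set drawn from a common universe (`P[X >= observed]`), plus the
#' relative enrichment = observed / expected overlap.
#'
#' @param query,annotation,universe character vectors of gene ids; query and
#'   annotation must be subsets of the universe.
#' @return list of class `enrichment_result` (partial: no permutation p):
#'   `n_query`, `n_annotation`, `n_universe`, `overlap`,
#'   `relative_enrichment`, `p.value`.
#' @export
hypergeom_enrichment <- function(query, annotation, universe) {
  if (length(universe) == 0) .stopf("empty universe")
  query <- unique(query); annotation <- unique(annotation)
  universe <- unique(universe)
  if (!all(query %in% universe)) .stopf("query is not a subset of universe")
  if (!all(annotation %in% universe)) {
    .stopf("annotation is not a subset of universe")
  }
  k <- length(intersect(query, annotation))
  nq <- length(query); na <- length(annotation); nu <- length(universe)
  p <- stats::phyper(k - 1, na, nu - na, nq, lower.tail = FALSE)
  expected <- nq * na / nu
  structure(list(n_query = nq, n_annotation = na, n_universe = nu,
                 overlap = k,
                 relative_enrichment = if (expected > 0) k / expected else
                   NA_real_,
                 p.value = p),
            class = "enrichment_result")
}

#' Expression-matched permutation p value for a gene-set overlap
#'
#' Bins the universe by expression deciles (the number of bins is
#' configurable) and draws, B times, a random gene set with the query's
#' per-bin composition; the permutation p value is
#' `(1 + #\{permuted overlap >= observed\}) / (B + 1)`. This controls for
#' expression level as a confounder of gene-set overlap.
#'
#' @param query,annotation,universe gene-id vectors (subsets of universe).
#' @param expression named per-gene expression level covering the universe.
#' @param B number of permutations (default 1000).
#' @param n_bins number of expression bins (default 10 = deciles).
#' @param seed integer seed.
#' @return permutation p value in `[1/(B+1), 1]`.
#' @export
matched_permutation_p <- function(query, annotation, universe, expression,
                                  B = 1000, n_bins = 10, seed = 1) {
  query <- unique(query); annotation <- unique(annotation)
  universe <- unique(universe)
  if (!all(query %in% universe)) .stopf("query is not a subset of universe")
  if (!all(universe %in% names(expression))) {
    .stopf("expression must be named and cover the universe")
  }
  e <- expression[universe]
  br <- unique(stats::quantile(e, probs = seq(0, 1, length.out = n_bins + 1)))
  bin <- cut(e, breaks = br, include.lowest = TRUE, labels = FALSE)
  names(bin) <- universe
  qbin <- table(factor(bin[query], levels = sort(unique(bin))))
  ubins <- split(universe, bin)
  for (b in names(qbin)) {
    if (qbin[[b]] > length(ubins[[b]])) {
      .stopf("expression bin %s has %d genes but the query needs %d draws",
             b, length(ubins[[b]]), qbin[[b]])
    }
  }
  obs <- length(intersect(query, annotation))
  is_ann <- stats::setNames(universe %in% annotation, universe)
  set.seed(seed)
  perm <- vapply(seq_len(B), function(i) {
    hits <- 0L
    for (b in names(qbin)) {
      nb <- qbin[[b]]
      if (nb > 0) {
        draw <- sample(ubins[[b]], nb)
        hits <- hits + sum(is_ann[draw])
      }
    }
    hits
  }, 0L)
  (1 + sum(perm >= obs)) / (B + 1)
}

#' Multiple-testing significance filter for enrichment results
#'
#' An enrichment is flagged significant iff its hypergeometric p value is
#' below `alpha / (n_lists * n_gene_groups)` (Bonferroni over the tested
#' list-by-group grid) and its permutation p value is below `perm_alpha`.
#'
#' @param hyper_p,perm_p vectors of hypergeometric and permutation p values.
#' @param n_lists number of annotation lists tested.
#' @param n_gene_groups number of query gene groups tested.
#' @param alpha family-wise level before correction (default 0.05).
#' @param perm_alpha permutation-p threshold (default 0.05).
#' @return list `threshold`, `significant` (logical vector).
#' @export
significance_filter <- function(hyper_p, perm_p, n_lists, n_gene_groups,
                                alpha = 0.05, perm_alpha = 0.05) {
  stopifnot(alpha > 0, perm_alpha > 0, n_lists > 0, n_gene_groups > 0)
  threshold <- alpha / (n_lists * n_gene_groups)
  list(threshold = threshold,
       significant = hyper_p < threshold & perm_p < perm_alpha)
}

#' Two-proportion chi-square test
#'
#' 2x2 chi-square test with Yates continuity correction (df = 1) for a
#' difference between two proportions `k1/n1` and `k2/n2`.
#'
#' @param k1,n1 successes and trials in group 1.
#' @param k2,n2 successes and trials in group 2.
#' @return list `statistic`, `p.value`.
#' @export
two_proportion_test <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) .stopf("group sizes must be positive")
  stopifnot(k1 >= 0, k1 <= n1, k2 >= 0, k2 <= n2)
  ht <- suppressWarnings(
    stats::prop.test(c(k1, k2), c(n1, n2), correct = TRUE))
  list(statistic = unname(ht$statistic), p.value = ht$p.value)
}

#' Sharing of sex-DE by X-inactivation class
#'
#' Tabulates, for each XCI class (escape, inactive, variable, unknown,
#' autosomal), how many genes were classified as shared sex-DE versus not,
#' and tests every pair of classes for a difference in the shared proportion
#' with the Yates-corrected chi-square test. Classes with zero genes are
#' omitted with a warning.
#'
#' @param categories per-gene life-stage category (from [classify_genes()]),
#'   named by gene or aligned with `xci_class`.
#' @param xci_class per-gene XCI class labels.
#' @param shared_categories category labels counted as shared (default
#'   `"shared"`).
#' @return list `table` (class, n_shared, n_total, pct_shared) and `tests`
#'   (pairwise class comparisons with chi-square statistic and p value).
#' @export
xci_category_table <- function(categories, xci_class,
                               shared_categories = "shared") {
  stopifnot(length(categories) == length(xci_class))
  shared <- categories %in% shared_categories
  classes <- if (is.factor(xci_class)) levels(xci_class) else
    unique(xci_class)
  xci_class <- as.character(xci_class)
  n_tot <- vapply(classes, function(cl) sum(xci_class == cl), 0L)
  empty <- n_tot == 0
  if (any(empty)) {
    warning("omitting XCI class(es) with 0 genes: ",
            paste(classes[empty], collapse = ", "))
    classes <- classes[!empty]
  }
  tab <- data.frame(
    class = classes,
    n_shared = vapply(classes, function(cl) sum(shared[xci_class == cl]), 0L),
    n_total = vapply(classes, function(cl) sum(xci_class == cl), 0L),
    stringsAsFactors = FALSE, row.names = NULL)
  tab$pct_shared <- 100 * tab$n_shared / tab$n_total
  tests <- NULL
  if (length(classes) >= 2) {
    cmb <- utils::combn(classes, 2)
    tests <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
      a <- cmb[1, i]; b <- cmb[2, i]
      ia <- match(a, tab$class); ib <- match(b, tab$class)
      tt <- two_proportion_test(tab$n_shared[ia], tab$n_total[ia],
                                tab$n_shared[ib], tab$n_total[ib])
      data.frame(class1 = a, class2 = b, statistic = tt$statistic,
                 p.value = tt$p.value, stringsAsFactors = FALSE)
    }))
  }
  list(table = tab, tests = tests)
}
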