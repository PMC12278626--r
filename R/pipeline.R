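#' Join prenatal and adult effect estimates into an effect-pair table
#'
#' Selects the union of the genes significant (q below the threshold) in
#' either sex-DE table and returns both logFCs and standard errors per gene.
#' Genes missing from either table's tested universe are dropped; the count
#' is recorded in the `n_dropped` attribute.
#'
#' @param de_prenatal,de_adult sex-DE tables (`gene_id, logFC, SE, qvalue`).
#' @param q_threshold significance threshold (default 0.01).
#' @return data.frame `gene_id, b1, se1, b2, se2` (axis 1 = prenatal).
#' @export
effect_pair_join <- function(de_prenatal, de_adult, q_threshold = 0.01) {
  sig <- union(de_prenatal$gene_id[de_prenatal$qvalue < q_threshold],
               de_adult$gene_id[de_adult$qvalue < q_threshold])
  if (length(sig) == 0) {
    .stopf("no genes significant at q < %g in either dataset", q_threshold)
  }
  keep <- sig[sig %in% de_prenatal$gene_id & sig %in% de_adult$gene_id]
  n_dropped <- length(sig) - length(keep)
  if (length(keep) == 0) .stopf("no significant gene is tested in both")
  i1 <- match(keep, de_prenatal$gene_id)
  i2 <- match(keep, de_adult$gene_id)
  out <- data.frame(gene_id = keep,
                    b1 = de_prenatal$logFC[i1], se1 = de_prenatal$SE[i1],
                    b2 = de_adult$logFC[i2], se2 = de_adult$SE[i2],
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' End-to-end composition of the workflow on simulated data: simulate the
#' prenatal and adult cohorts, assign sample sex from the marker genes, drop
#' unassigned samples and the marker genes, filter and normalize counts,
#' infer pseudotime per cohort, run the per-gene DE analysis (sex,
#' pseudotime, interaction), join the union of sex-DE genes into an
#' effect-pair table, fit the line-model mixture by Gibbs sampling, classify
#' genes, and compute the cross-stage comparison report and the XCI-class
#' sharing table. All randomness derives from `config$seed`; identical
#' configurations give identical results. If `out_dir` is given, the main
#' tables are written there as TSV files.
#'
#' @param config a [simulation_config()].
#' @param thresholds a [sex_check_thresholds()]; the default (chrY sum 1000,
#'   XIST 150) suits the simulated marker depths.
#' @param n_variable_genes number of variable genes for the trajectory fit.
#' @param q_threshold DE significance threshold.
#' @param n_iter,burn_in Gibbs iterations and burn-in.
#' @param out_dir optional output directory for TSV files.
#' @return list with per-stage components (`sim`, `sexcheck`, `norm`,
#'   `trajectory`, `de`), the effect-pair table, `scale`, the
#'   `line_model_result`, `categories`, `comparison`, `xci` and an
#'   `enrichment` demonstration (shared genes vs XCI escapees,
#'   expression-matched permutation background).
#' @export
run_pipeline <- function(config = simulation_config(),
                         thresholds = sex_check_thresholds(
                           chry_sum_cutoff = 1000, xist_cutoff = 150),
                         n_variable_genes = 500,
                         q_threshold = 0.01,
                         n_iter = 2000L, burn_in = 200L,
                         out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))

  run_stage <- function(stage) {
    sim <- simulate_counts(config, stage)
    sexcheck <- assign_sex(sim$counts, sim$genes, thresholds)
    keep_s <- sexcheck$assigned_sex != "unassigned"
    samples <- sim$samples[keep_s, , drop = FALSE]
    samples$sex_assigned <- sexcheck$assigned_sex[keep_s]
    marker <- sim$genes$is_xist | sim$genes$is_chry_marker
    counts <- sim$counts[!marker, keep_s, drop = FALSE]
    norm <- normalize_counts(counts)
    k <- min(n_variable_genes, nrow(norm$logcpm) - 1L)
    traj_genes <- select_variable_genes(norm, k)
    fit <- fit_trajectory(norm$logcpm[traj_genes, , drop = FALSE],
                          samples$sex_assigned)
    anchor <- if (stage == "prenatal") samples$time else NULL
    fit <- suppressWarnings(orient_pseudotime(fit, anchor))
    de <- fit_gene_models(norm, sex = samples$sex_assigned,
                          pseudotime = fit$z,
                          individual_id = samples$individual_id,
                          exclude_from_pseudotime = traj_genes,
                          q_threshold = q_threshold)
    list(sim = sim, sexcheck = sexcheck, samples = samples, norm = norm,
         trajectory_genes = traj_genes, trajectory = fit, de = de)
  }

  prenatal <- run_stage("prenatal")
  adult <- run_stage("adult")

  pairs <- effect_pair_join(prenatal$de$sex, adult$de$sex,
                            q_threshold = q_threshold)
  sig1 <- prenatal$de$sex$logFC[prenatal$de$sex$significant]
  scale <- if (length(sig1)) compute_scale(sig1) else LINEMODEL_SCALE_DEFAULT
  lm_config <- line_model_config(models = default_line_models(scale = scale),
                                 n_iter = n_iter, burn_in = burn_in,
                                 seed = config$seed + 7919L)
  lm_res <- gibbs_proportions(pairs, lm_config)
  categories <- classify_genes(lm_res$pp)

  comparison <- compare_sexde(prenatal$de$sex, adult$de$sex,
                              q_threshold = q_threshold)

  genes <- prenatal$sim$genes
  xci_class <- genes$xci_class[match(categories$gene_id, genes$gene_id)]
  xci <- suppressWarnings(xci_category_table(categories$category, xci_class))

  # demonstration enrichment: are shared-category genes enriched in XCI
  # escapees, against an expression-matched background?
  universe <- intersect(prenatal$de$sex$gene_id, adult$de$sex$gene_id)
  query <- intersect(categories$gene_id[categories$category == "shared"],
                     universe)
  annotation <- intersect(genes$gene_id[genes$xci_class == "escape"],
                          universe)
  enrichment <- NULL
  if (length(query) > 0 && length(annotation) > 0) {
    expr <- rowMeans(prenatal$norm$logcpm)[universe]
    hy <- hypergeom_enrichment(query, annotation, universe)
    pp <- matched_permutation_p(query, annotation, universe, expr,
                                B = 1000, seed = config$seed + 10007L)
    enrichment <- list(hypergeom = hy, permutation_p = pp)
  }

  res <- list(prenatal = prenatal, adult = adult, pairs = pairs,
              scale = scale, linemodels = lm_res, categories = categories,
              comparison = comparison, xci = xci, enrichment = enrichment,
              config = config)

  if (!is.null(out_dir)) .write_pipeline_tsvs(res, out_dir)
  res
}

#' @keywords internal
#' @noRd
.write_pipeline_tsvs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, name) {
    utils::write.table(x, file.path(out_dir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (stage in c("prenatal", "adult")) {
    st <- res[[stage]]
    wt(st$sexcheck, paste0(stage, "_sexcheck"))
    wt(data.frame(sample_id = names(st$trajectory$z),
                  pseudotime = as.numeric(st$trajectory$z)),
       paste0(stage, "_pseudotime"))
    for (term in c("sex", "pseudotime", "interaction")) {
      wt(st$de[[term]], paste0(stage, "_de_", term))
    }
  }
  wt(res$pairs, "effect_pairs")
  pp <- as.data.frame(res$linemodels$pp)
  pp <- cbind(gene_id = rownames(res$linemodels$pp), pp)
  wt(pp, "posterior_probabilities")
  wt(data.frame(model = names(res$linemodels$proportions),
                estimate = as.numeric(res$linemodels$proportions),
                se = as.numeric(res$linemodels$proportions_se)),
     "proportions")
  wt(res$categories, "categories")
  invisible(NULL)
}
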