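#' Sex-check thresholds
#'
#' Raw-count cutoffs used to assign genetic sex from marker-gene expression.
#' The symmetric single-cutoff rule (7000/7000) is the one used for the
#' prenatal cohort; a two-cutoff rule (XIST 150, chrY sum 1000) is used for
#' the adult cohort whose sequencing depth differs.
#'
#' @param chry_sum_cutoff cutoff on the summed counts of chromosome-Y
#'   protein-coding genes.
#' @param xist_cutoff cutoff on the XIST count.
#' @return list of class `sex_check_thresholds`.
#' @export
sex_check_thresholds <- function(chry_sum_cutoff = 7000, xist_cutoff = 7000) {
  stopifnot(chry_sum_cutoff > 0, xist_cutoff > 0)
  structure(list(chry_sum_cutoff = chry_sum_cutoff,
                 xist_cutoff = xist_cutoff),
            class = "sex_check_thresholds")
}

#' Assign genetic sex from marker-gene counts
#'
#' A sample is labelled male if its summed chromosome-Y protein-coding counts
#' exceed the chrY cutoff while its XIST count is below the XIST cutoff;
#' female if chrY is below and XIST above; otherwise `unassigned` (such
#' samples are excluded downstream).
#'
#' @param counts genes x samples count matrix with gene-id rownames.
#' @param gene_table data.frame with `gene_id` and logical columns `is_xist`
#'   and `is_chry_marker` identifying the marker genes.
#' @param thresholds a [sex_check_thresholds()].
#' @return data.frame: sample_id, chry_sum, xist_count, assigned_sex
#'   (`male`/`female`/`unassigned`).
#' @export
assign_sex <- function(counts, gene_table,
                       thresholds = sex_check_thresholds()) {
  stopifnot(inherits(thresholds, "sex_check_thresholds"))
  if (!all(c("is_xist", "is_chry_marker") %in% names(gene_table))) {
    .stopf("gene_table must carry 'is_xist' and 'is_chry_marker' columns")
  }
  xist_id <- gene_table$gene_id[gene_table$is_xist]
  chry_id <- gene_table$gene_id[gene_table$is_chry_marker]
  if (length(xist_id) != 1) {
    .stopf("gene_table must flag exactly one XIST-like gene (found %d)",
           length(xist_id))
  }
  if (length(chry_id) == 0) {
    .stopf("gene_table flags no chrY protein-coding marker genes")
  }
  missing <- setdiff(c(xist_id, chry_id), rownames(counts))
  if (length(missing)) {
    .stopf("marker genes absent from the count matrix: %s",
           paste(missing, collapse = ", "))
  }
  xist <- counts[xist_id, ]
  chry <- colSums(counts[chry_id, , drop = FALSE])
  male <- chry > thresholds$chry_sum_cutoff & xist < thresholds$xist_cutoff
  female <- chry < thresholds$chry_sum_cutoff & xist > thresholds$xist_cutoff
  assigned <- ifelse(male, "male", ifelse(female, "female", "unassigned"))
  data.frame(sample_id = colnames(counts), chry_sum = as.numeric(chry),
             xist_count = as.numeric(xist), assigned_sex = assigned,
             stringsAsFactors = FALSE)
}

#' Counts per million
#'
#' @param counts genes x samples count matrix.
#' @return matrix of CPM values; every column sums to 1e6.
#' @export
cpm <- function(counts) {
  lib <- colSums(counts)
  if (any(lib <= 0)) {
    .stopf("zero library size in sample(s): %s",
           paste(colnames(counts)[lib <= 0], collapse = ", "))
  }
  t(t(counts) / lib) * 1e6
}

#' Low-expression filter
#'
#' Keeps a gene iff its CPM exceeds 1 in strictly more than `min_samples`
#' samples.
#'
#' @param counts genes x samples count matrix.
#' @param min_samples strict threshold on the number of samples with CPM > 1
#'   (default 10).
#' @return logical kept-gene mask, named by gene.
#' @export
filter_low_expression <- function(counts, min_samples = 10) {
  n_above <- rowSums(cpm(counts) > 1)
  stats::setNames(n_above > min_samples, rownames(counts))
}

#' TMM normalization factors
#'
#' Trimmed-mean-of-M-values between-sample normalization factors (the
#' standard weighted TMM algorithm: 30%/5% trimming on M/A values, reference
#' sample chosen by upper-quartile proximity to the mean upper quartile,
#' inverse-variance weighting). Factors are scaled so their geometric mean
#' is 1.
#'
#' @param counts genes x samples count matrix (>= 2 samples).
#' @param reference optional sample id to use as the reference column.
#' @return named numeric vector of per-sample normalization factors.
#' @export
tmm_factors <- function(counts, reference = NULL) {
  if (ncol(counts) < 2) .stopf("TMM requires at least 2 samples")
  lib <- colSums(counts)
  if (is.null(reference)) {
    # reference = sample whose upper quartile (of depth-scaled counts) is
    # closest to the mean upper quartile
    uq <- apply(counts, 2, stats::quantile, probs = 0.75) / lib
    ref_col <- which.min(abs(uq - mean(uq)))
  } else {
    ref_col <- match(reference, colnames(counts))
    if (is.na(ref_col)) .stopf("reference sample '%s' not found", reference)
  }
  shared <- colSums(counts > 0 & counts[, ref_col] > 0)
  if (any(shared == 0)) {
    .stopf("sample(s) sharing no expressed genes with the reference: %s",
           paste(colnames(counts)[shared == 0], collapse = ", "))
  }
  f <- edgeR::calcNormFactors(counts, method = "TMM", refColumn = ref_col)
  stats::setNames(as.numeric(f), colnames(counts))
}

#' Log2 counts per million with a prior count
#'
#' `log2((count + prior_count) / (library_size * tmm_factor) * 1e6)`. Finite
#' everywhere for `prior_count > 0` and monotone in the counts.
#'
#' @param counts genes x samples count matrix.
#' @param tmm optional per-sample TMM factors (default: computed).
#' @param prior_count pseudo-count added before taking logs (default 0.5).
#' @return list of class `normalized_matrix`: `logcpm` (matrix), `tmm`,
#'   `library_size`, `prior_count`.
#' @export
log_cpm <- function(counts, tmm = NULL, prior_count = 0.5) {
  if (is.null(tmm)) tmm <- tmm_factors(counts)
  lib <- colSums(counts)
  eff <- lib * tmm
  logcpm <- log2(t((t(counts) + prior_count) / eff) * 1e6)
  structure(list(logcpm = logcpm, tmm = tmm, library_size = lib,
                 prior_count = prior_count),
            class = "normalized_matrix")
}

#' Filter and normalize a count matrix
#'
#' Convenience wrapper: applies the low-expression filter (CPM > 1 in more
#' than `min_samples` samples), computes TMM factors on the kept genes, and
#' returns log2-CPM values.
#'
#' @inheritParams log_cpm
#' @inheritParams filter_low_expression
#' @return a `normalized_matrix` with an additional `kept` logical mask over
#'   the input genes.
#' @export
normalize_counts <- function(counts, min_samples = 10, prior_count = 0.5) {
  kept <- filter_low_expression(counts, min_samples = min_samples)
  if (!any(kept)) .stopf("no genes pass the expression filter")
  norm <- log_cpm(counts[kept, , drop = FALSE], prior_count = prior_count)
  norm$kept <- kept
  norm
}
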