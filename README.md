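# brainsexde

Tools for quantifying **sex-differential gene expression (sex-DE)** in bulk
RNA-seq cohorts from two life stages of the human forebrain, and for
classifying how each gene's female/male effect is **shared between prenatal
and adult brain**. The package is aimed at analysts who have gene-level
count matrices from two cohorts (e.g. a developmental resource and an adult
biobank) and want the full chain: sample sex verification, normalization, a
developmental pseudotime covariate, per-gene DE, and a Bayesian
classification of cross-stage effect sharing — plus a simulator with known
ground truth to validate every step.

## The model at the core

For each gene the two cohorts give an observed effect pair
`b = (b_prenatal, b_adult)` (log2 female/male fold changes, positive =
female-biased) with standard errors `(se1, se2)`. Each sharing hypothesis is
a **line model**: a zero-mean bivariate Gaussian prior concentrated along a
line through the origin,

- `PRENATAL` (slope 0) and `ADULT` (slope ∞): effect in one dataset only,
- `SHARED1` (slope 1): equal effects; `SHARED0.5` / `SHARED2` (slopes
  0.5 / 2): shared with a factor-2 magnitude asymmetry,
- `OPPOSITE` (slope −1): equal magnitude, opposite direction.

Each model has covariance built from its slope, a scale (prior SD of the
larger effect; default 0.1971916 = 95th percentile of prenatal |logFC| / 2)
and a line-concentration correlation (0.995; 0.990 for `OPPOSITE`). The
marginal likelihood of a gene under model `k` is
`N(b; 0, Sigma_prior(k) + Sigma_obs)`, and a Gibbs sampler (2000 iterations,
200 burn-in) alternates per-gene model assignments with Dirichlet draws of
the mixture proportions, yielding proportion estimates ± SE and per-gene
posterior probabilities. Genes are classified at posterior probability
> 0.8 (the three shared models summed for the `shared` call).

Upstream of that, per-gene effects come from
`expression ~ sex + pseudotime + sex:pseudotime` with cluster-robust (CR1)
standard errors over individuals, Storey q-values (`q < 0.01`), and a
latent pseudotime fit by penalized alternating least squares with sex as an
interacting covariate. Sample sex is assigned from XIST and chrY
protein-coding counts; normalization is TMM + log2-CPM with the
CPM > 1 in > 10 samples filter.

## Worked example

Everything below runs on simulated data with known truth — no downloads.

```r
library(brainsexde)

cfg <- simulation_config(seed = 11)   # two cohorts, 2000 genes, known mixture
res <- run_pipeline(cfg)

round(100 * res$linemodels$proportions, 1)
#>  PRENATAL SHARED0.5   SHARED1   SHARED2     ADULT  OPPOSITE
#>      64.2      25.6       4.9       0.2       0.1       5.1

table(res$categories$category)
#>          opposite prenatal-specific            shared      unclassified
#>                49               722               251               304

stage_correlation(res$prenatal$trajectory$z, res$prenatal$samples$time)$tau
#> [1] 0.899

res$xci$table
#>       class n_shared n_total pct_shared
#> 1    escape       13      16   81.25000
#> 2  inactive        8      40   20.00000
#> 3 autosomal      230    1270   18.11024
```

Reading the output: the Gibbs mixture attributes 64.2% of the sex-DE signal
to prenatal-specific effects and 30.7% to shared effects (dominated by
`SHARED0.5`, i.e. effects twice as large prenatally) — close to the
generating truth of 60% / 28% / 2% (the analyzed genes are the union of
genes significant in either cohort, so the realized truth among them differs
slightly from the configured mixture). The inferred pseudotime orders the
prenatal samples almost exactly along their true developmental times
(Kendall tau 0.90). Simulated XCI escapees, which carry lifelong
female-biased effects by construction, are classified `shared` far more
often (81%) than inactive X or autosomal genes (~20%, the shared fraction in
the rest of the mixture) — the signature the classifier is designed to
expose.

Individual stages are exported directly: `assign_sex()`,
`normalize_counts()`, `select_variable_genes()` / `fit_trajectory()` /
`orient_pseudotime()`, `fit_gene_models()`, `storey_qvalues()` /
`pi1_replication()`, `effect_pair_join()`, `gibbs_proportions()` /
`classify_genes()`, `compare_sexde()`, `hypergeom_enrichment()` /
`matched_permutation_p()`, `two_proportion_test()` / `xci_category_table()`.
See the vignette (`vignettes/sex-de-sharing.Rmd`) for the models,
assumptions and numerical choices.

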