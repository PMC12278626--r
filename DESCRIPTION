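Package: brainsexde
Title: Sex-Differential Expression Sharing Across Brain Life Stages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify sex-differential gene expression (sex-DE) in
    bulk RNA-seq cohorts from two life stages of the human forebrain and to
    classify how each gene's female/male effect is shared between them.
    Provides marker-gene-based sample sex assignment (XIST and chromosome-Y
    counts), TMM/CPM normalization and expression filtering, a
    covariate-adjusted latent pseudotime fit by penalized alternating least
    squares, per-gene differential expression for sex, pseudotime and their
    interaction with cluster-robust standard errors for repeated samples per
    individual, Storey q-values and pi1 replication rates, a Bayesian
    line-model mixture (prenatal-specific, shared at 0.5x/1x/2x magnitude,
    adult-specific, opposite) with Gibbs estimation of mixture proportions,
    cross-stage comparison statistics, expression-matched permutation
    enrichment, and a negative-binomial cohort simulator with known ground
    truth for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    edgeR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
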