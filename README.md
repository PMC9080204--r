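# lggproteo

Downstream proteogenomic analysis of diffuse low-grade glioma (LGG)
molecular subtypes, for researchers working with multiplexed (TMT) protein
abundance matrices and, optionally, matched bulk RNA expression.

LGG splits into three molecular subtypes: IDH-mutant with 1p/19q codeletion
(oligodendroglioma, `TYPE_I`), IDH-mutant 1p/19q-retained (astrocytoma,
`TYPE_II`) and IDH-wildtype (`TYPE_III`). The codeletion removes one copy
of every gene on chromosome arms 1p and 19q; the package quantifies how
that dosage loss propagates — strongly into the transcriptome, attenuated
into the proteome — and builds a protein-based subtype classifier.

## What it computes

- **Complete-case filtering** — a protein is kept only if identified in all
  MS runs (`filter_complete_features()`); no imputation is performed.
- **Differential abundance** (`de_test()`) — per-feature Welch t-test on
  log2 values, significant iff |log2FC| > log2(1.5) **and** BH-adjusted
  p < cutoff (0.05 for protein, 0.01 for RNA). BH is applied across all
  tested features (`benjamini_hochberg()`).
- **Arm localization** (`localize_de()`) — up/down counts and the
  down-fraction per chromosome arm (1p/1q/19p/19q/other), with a Fisher
  exact test of (on-arm) × (direction) per arm.
- **Combined 1p/19q z-score** (`combined_zscore()`) — per sample, the mean
  over 1p∪19q proteins of z-scores against a normal-brain reference:
  z̄(s) = mean over f of (x_fs − μ_f^NORMAL)/σ_f^NORMAL. Codeleted tumours
  score lowest. Group differences via `compare_score_groups()`.
- **RNA–protein coupling** (`arm_rna_protein_regression()`) — per arm, OLS
  of mean protein on mean RNA across genes within a subtype; R² quantifies
  dosage attenuation.
- **Marker panels** (`select_markers()`) — proteins significant and
  directionally concordant in at least two of the three pairwise subtype
  contrasts, assigned to the subtype the two contrasts share.
- **Subtype classifier** (`fit_multinomial()`, `cross_validate()`) — ridge
  multinomial regression on the panel, stratified 10-fold CV, one-vs-rest
  ROC curves and one-vs-one AUC per subtype pair (`roc_auc()`).
- **Unsupervised structure** (`top_mad_features()`,
  `hierarchical_cluster()`) — top-500 features by median absolute
  deviation, hierarchical clustering of z-scored profiles.
- **Synthetic cohorts** (`simulate_cohort()`, `simulate_missingness()`) —
  a generator emulating the study design (6 normal brain + 21/17/10
  tumours, 6000 proteins, planted dosage and marker effects, run-level
  dropout) with full ground truth, so every stage is testable offline.
- **One-call pipeline** (`run_all()`) — chains all stages and writes TSV
  outputs plus a JSON report.

## Worked example

```r
library(lggproteo)

co <- simulate_cohort(simulation_params(seed = 42))
protein <- filter_complete_features(co$protein)

r12 <- de_test(protein, co$samples, "TYPE_I", "TYPE_II")
r12
#> de_result: TYPE_I vs TYPE_II, 6000 features, 115 significant (|log2FC| > 0.585, padj < 0.05)

panel <- select_markers(
  r12,
  de_test(protein, co$samples, "TYPE_I", "TYPE_III"),
  de_test(protein, co$samples, "TYPE_II", "TYPE_III"))
summarize_panel(panel)
#> # A tibble: 5 × 3
#>   subtype  direction     n
#>   <chr>    <chr>     <int>
#> 1 TYPE_I   DOWN         17
#> 2 TYPE_I   UP           19
#> 3 TYPE_II  UP           18
#> 4 TYPE_III DOWN          2
#> 5 TYPE_III UP           18

scores <- combined_zscore(protein, co$samples, co$arms)
tapply(scores$z_combined, co$samples$subtype, mean)
#>        NORMAL        TYPE_I       TYPE_II      TYPE_III
#> -1.296342e-16 -8.572543e-01 -7.150075e-02 -2.342361e-02

tum <- co$samples[co$samples$subtype != "NORMAL", ]
X <- t(unclass(protein)[unique(panel$feature_id), tum$sample_id])
cv <- cross_validate(X, tum$subtype, cv_folds = 10, ridge_lambda = 1, seed = 42)
cv$auc_pairwise
#> # A tibble: 3 × 3
#>   class_a class_b    auc
#>   <chr>   <chr>    <dbl>
#> 1 TYPE_I  TYPE_II      1
#> 2 TYPE_I  TYPE_III     1
#> 3 TYPE_II TYPE_III     1
```

Reading the output: the I-vs-II contrast finds 115 differential proteins —
planted markers plus the 1p/19q dosage tail. The concordance panel
recovers the planted markers of all three subtypes (the `TYPE_I DOWN`
entries are 1p/19q proteins, exactly as a codeletion signature should
look). The combined z-score singles out `TYPE_I` (−0.86, everything else
near 0), and the panel separates the simulated subtypes perfectly under
cross-validation — the generator's planted effects are deliberately
clean; real cohorts report pairwise AUCs near 0.84–0.95.

The mechanics of each stage, parameter meanings and the generator's
statistical model are documented in
`vignettes/lgg-proteomic-subtyping.Rmd`.

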