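---
title: "Proteogenomic subtyping of low-grade glioma: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteogenomic subtyping of low-grade glioma: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Diffuse low-grade gliomas (LGG, WHO grade 2/3) fall into three molecular
subtypes: IDH-mutant tumours with whole-arm codeletion of chromosomes 1p and
19q (oligodendroglioma, here `TYPE_I`), IDH-mutant 1p/19q-retained tumours
(astrocytoma, `TYPE_II`), and IDH-wildtype tumours (`TYPE_III`). The 1p/19q
codeletion removes one copy of every gene on those arms, which depresses
their transcript levels strongly; at the protein level the same dosage loss
is visible but attenuated by translational buffering. `lggproteo` implements
the downstream analysis chain that quantifies these observations from a
protein abundance matrix (typically multiplexed TMT mass spectrometry,
pre-normalized upstream) with an optional matched RNA matrix:

1. complete-case filtering (a protein must be identified in every MS run);
2. pairwise differential abundance with a fold-change gate and BH-FDR;
3. localization of differential features to chromosome arms, with a Fisher
   exact test per arm;
4. a combined 1p/19q z-score per sample against a normal-brain reference;
5. per-arm regression of mean protein on mean RNA expression;
6. directional-concordance selection of subtype marker panels;
7. a ridge multinomial classifier with stratified cross-validation and
   ROC/AUC;
8. MAD-based feature selection and hierarchical clustering.

Every stage is exercised end-to-end by a synthetic cohort generator with
planted ground truth, so the whole pipeline is testable without any
external download.

# Statistical procedures

## Differential testing

`de_test()` runs a per-feature Welch two-sample t-test on log2 values.
Counts-based RNA models (negative binomial, variance moderation) are out of
scope; Welch-on-log2 is the declared surrogate for RNA and the primary test
for protein abundance, where the underlying quantification is continuous.
A feature is significant iff both gates hold jointly:

* `|log2FC| > log2(fc_threshold)` with `fc_threshold = 1.5` (strict
  inequality, on the linear fold-change scale), and
* BH-adjusted p below the cutoff — 0.05 for protein differential abundance,
  0.01 for the RNA contrasts.

BH adjustment (`benjamini_hochberg()`) is applied across **all** features
tested in a contrast, not only those passing the fold-change gate; the two
gates are independent filters. Degenerate features with zero variance in
both groups get p = 1 when the group means are equal; with unequal means a
machine-epsilon variance floor keeps the statistic finite.

## Arm localization

`localize_de()` counts significant up/down features per arm label
(`1p`, `1q`, `19p`, `19q`, `other`) and tests each arm's 2x2 table
(on-arm vs off-arm) x (down vs up) with a two-sided Fisher exact test. The
source analyses plot the up/down ratio per arm; the Fisher test is this
package's formalization of "enrichment" (a testable statistic is needed),
and the raw `down_fraction` is reported alongside so ratio figures can be
reproduced. Features without an annotation are counted under `other` and
reported, never dropped silently.

## Combined 1p/19q z-score

For every feature on the target arms, `combined_zscore()` standardizes each
sample against the normal-brain reference,
`z = (x - mean(NORMAL)) / sd(NORMAL)` (n−1 denominator; reference features
with SD below 1e-8 are excluded), and averages z over the 1p∪19q features.
The unweighted per-feature mean is the simplest combination rule; the
median is available as an option for robustness. Two properties worth
knowing: the NORMAL group mean is exactly zero by construction
(self-referential centering), and the score is **not** invariant to
per-sample global shifts — a test asserts this sensitivity, because it
means sample-level normalization must precede scoring.

## RNA-protein coupling per arm

`arm_rna_protein_regression()` computes, within one subtype group, each
shared gene's mean RNA and mean protein expression over the group's
samples and fits OLS of mean protein on mean RNA per arm (protein is the
response). R² equals the squared Pearson correlation of the two mean
vectors — a closed-form identity the tests check to 1e-12. Arms with fewer
than 3 shared genes are skipped with a warning.

## Marker panel selection

`select_markers()` operates on the three pairwise tumour contrasts
(I vs II, I vs III, II vs III; orientations are validated, never inferred).
Any two of these contrasts share exactly one subtype, so "significant and
directionally concordant in at least two comparisons" resolves per subtype
S to: significant in both contrasts involving S with equal sign once
directions are re-expressed relative to S. Two rules ship:

* `any_two` (default): every qualifying subtype yields an assignment, so a
  stepwise feature (monotone across the three subtypes, like the classic
  intermediate-filament markers) can legitimately receive two assignments,
  e.g. `TYPE_I`-DOWN and `TYPE_III`-UP;
* `strict_both`: only features with a unique qualifying subtype are kept.

`strict_both` output is provably a subset of `any_two` output. The
published panel counts (27 Type I markers against only 24 significant
proteins in the I-vs-II contrast) cannot be produced by the strict reading,
which is why the dual-assignment rule is the default; the exhaustive 27-case
sign-pattern truth table is frozen in the tests.

## Classifier

`fit_multinomial()` maximizes the L2-penalized multinomial log-likelihood
(softmax regression, reference-class parametrization, intercepts
unpenalized) with BFGS to gradient tolerance 1e-6; the problem is convex,
so the fit is deterministic. With `ridge_lambda = 0` on separable data the
likelihood has no maximizer; this is detected through probability
saturation and reported with guidance to use a positive penalty. The
default `ridge_lambda = 1` on standardized features reflects the problem
geometry — with ~50 panel features and ~48 tumour samples an unpenalized
fit is frequently separable.

`cross_validate()` makes seeded stratified folds (default 10), standardizes
features on each training split (train mean/SD applied to the held-out
split), and pools out-of-fold probabilities into a single ROC per class
(one-vs-rest) plus one-vs-one AUCs per class pair computed on the two
classes' samples with the renormalized probability as score. Pairwise AUC
is the headline metric since subtype distinguishability is a pairwise
question; one-vs-rest curves serve the usual ROC figure. AUC uses the
Mann-Whitney midrank formulation, checked against brute-force concordant
pair counting to 1e-12.

## Unsupervised structure

`top_mad_features()` ranks by `median(|x - median(x)|)` (no consistency
constant) with lexicographic tie-breaks; the default keeps 500 features.
`hierarchical_cluster()` z-scores the selected features and clusters
samples; the default is Euclidean distance with average linkage. Euclidean
on z-scored features (the default of the common heatmap tools) is
deliberately chosen over correlation distance: correlation keys on the
single strongest shared profile axis, which in this setting is the
codeletion signature and splits Type I from everything else, whereas the
magnitude-sensitive Euclidean view recovers the tissue-level structure
(normal brain apart from all tumours) that dominates real cohorts. Both
distances and three linkages are available, and `k` for label extraction
is an analyst choice with no claim of correctness — dendrogram inspection
is the primary readout.

# The synthetic cohort generator

`simulate_cohort()` emulates the study conditions: 6 normal brain, 21
Type I, 17 Type II, 10 Type III samples and 6000 features, of which 4.5% /
5.5% / 3% / 3.5% sit on 1p / 1q / 19p / 19q. Per feature f and sample s the
log2 abundance is

```
baseline_f + tumour_shift_f·[s tumour] + subtype_shift_{f,g(s)}
  + dosage·[f on 1p∪19q][g(s) = TYPE_I] + marker·[f planted for g(s)]
  + N(0, noise_sd)
```

with Gaussian-in-log2 noise throughout (the standard model for TMT
intensities and log RNA). Key parameters, each drawn once per feature where
applicable:

| parameter | default | role |
|---|---|---|
| `noise_sd` | 0.5 | per-measurement log2 SD, independent per omic |
| `biological_sd` | 0.3 | SD of the per-feature baseline, shared RNA/protein |
| `tumor_shift_sd` | 0.4 | tumour-vs-normal shift shared by all tumour samples |
| `subtype_shift_sd` | 0.1 | background per-subtype shifts (non-separating) |
| `dosage_effect_rna` | −1.0 | 1p/19q shift in Type I at RNA |
| `dosage_effect_protein` | −0.35 | same at protein: attenuated, not halved |
| `marker_effect` | +1.2 | planted marker shift in its subtype (20/subtype) |
| `rna_protein_decoupling_sd` | 1.0 | per-gene protein offset |

The dosage attenuation (−0.35 vs −1.0) encodes the qualitative finding that
codeletion is plainly visible in the transcriptome but buffered in the
proteome. The tumour-shared shift exists so that unsupervised clustering
has the tissue-level axis real cohorts show; it cancels exactly in every
tumour-vs-tumour contrast, so it changes no differential, marker, or
classifier behaviour.

The decoupling default is derived in closed form rather than fitted.
Writing `S` for the gene-level variance shared between omics within a
tumour group (`0.3² + 0.1² + 0.4² = 0.26`) and `U = noise_sd²/n_group ≈
0.012` for the group-mean noise, the across-gene R² of mean protein on
mean RNA is `S²/((S+U)(S+dec²+U))`; `dec = 1.0` puts it at ≈ 0.2, the
regime reported for all four arms (0.17–0.23). Raising the parameter
lowers R² monotonically (tested on a three-point grid).

`simulate_missingness()` models identification dropout at the MS-run
level: samples are grouped into consecutive runs of 9 (the per-run
multiplexing layout is not documented in the source cohort; 9 is a stated
placeholder), and each run blanks a random fraction of whole feature rows.
Its seed is scrambled internally (one LCG step) before seeding so that
passing the cohort's own seed cannot replay the cohort's random stream —
without this, the first dropout draw coincides with the generator's
arm-assignment permutation and deletes exactly the 1p/19q features.

## What the generator does and does not emulate

It reproduces: the cohort group sizes; log-normal measurement noise; a
complete-case-filter regime comparable to the published 7988→5894
reduction; arm-restricted dosage loss with protein attenuation;
subtype-specific markers recoverable by the concordance rule; tunable
RNA-protein decoupling; and tissue-level unsupervised structure. It does
not model peptide-level quantification, TMT ratio compression, batch or
plex effects, correlated co-regulation between features (features are
conditionally independent), or missingness mechanisms other than run-level
dropout. Passing tests therefore demonstrate the pipeline's correctness
and statistical calibration under a faithful null/effect model — not
robustness to every artefact of real TMT data.

# Numerical choices and degenerate inputs

* Fold-change gates use strict inequalities; BH ties are handled by rank
  with stable ordering and capped at 1.
* Zero-variance features: p = 1 in differential tests when means are equal
  (epsilon floor otherwise); excluded with a message from z-scoring and
  from clustering.
* MAD ties break lexicographically by feature ID so selections are
  deterministic.
* Matrices are written with 17 significant digits, making
  write-then-read bit-identical.
* The classifier restarts BFGS (up to 6 times) until the gradient norm is
  below 1e-6; non-convergence is an error with diagnostics, never a silent
  partial fit.
* All stochastic steps (simulation, fold splits, missingness) are
  deterministic given their seed.

# Problem sizes used in the shipped checks

The package's own validation runs at the generator's default scale
(6000 features x 54 samples). The frequency-style checks (z-score
separation, arm enrichment, marker recovery) use 50 generator seeds and
compare medians or success fractions against their thresholds; the
BH and AUC oracle equivalences use 1000 and 100 random instances; the
Welch calibration check uses 100,000 stacked null features. Four
reproduction checks against the published supplementary protein table
(filter count 7988→5894, differential counts 24/197/46, the 54-protein
panel, pairwise AUCs 0.944/0.949/0.840) require those tables to be
exported locally — see `tests/testthat/test-acceptance.R` for the expected
layout — and report a clear failure when the data are absent.

# Known limitations

* The Welch-on-log2 surrogate will not reproduce count-model results
  exactly on real RNA-seq; divergences on RNA contrasts are expected and
  documented rather than corrected.
* The combined z-score assumes sample-level normalization upstream.
* The concordance rule's published counts cannot be uniquely
  reconstructed from the text; both shipped rules and the discrepancy are
  documented, not resolved.
* With ~50 features and ~48 samples the classifier's AUC estimates carry
  substantial fold-split variance; seeds are explicit everywhere so runs
  are reproducible.
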