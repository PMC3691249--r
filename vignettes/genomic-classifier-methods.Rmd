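---
title: "Developing and validating a genomic classifier of early metastasis"
author: "metGC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing and validating a genomic classifier of early metastasis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metGC)
```

## The problem

After radical prostatectomy, a rising PSA (biochemical recurrence, BCR) is a
sensitive but unspecific signal: most men with BCR never develop clinical
metastasis, yet some progress within a few years and die of their disease.
`metGC` implements a complete pipeline for building and validating a
*genomic classifier* (GC) of early clinical metastasis from case-control
expression data — cases being men who metastasize within five years of BCR,
controls being men with BCR but no early metastasis (PSA group) or no
recurrence at all (NED group). Alongside the expression-based model it
builds a *clinical-only* logistic classifier (CC) from six standard
clinicopathologic variables and an *integrated* model (GCC) combining the
two, so that the added value of the genomic information can be quantified.

The pipeline's stages mirror how such classifiers are developed in
practice:

1. **Reliability filtering.** Features measured with fewer than four probes
   or flagged as cross-hybridizing are removed. Then the per-feature
   variance across technical replicate control profiles (a cell line run
   with each hybridization batch) is used to gauge technical versus
   biological variability: the top 10% most variable features on the
   controls are removed. Ties at the cutoff variance are all removed — a
   deterministic, conservative rule.
2. **Batch-effect removal.** The feature-centered matrix is decomposed by
   SVD into principal components over samples. For each of the first 10
   components, the association of its score vector with batch is the
   R-squared of a one-way ANOVA on batch label, and the two most
   batch-associated components are subtracted from the data. No rescaling
   follows the removal.
3. **Feature selection.** A per-feature two-sided t-test (Welch by default;
   pooled-variance is a switch) at p < 0.01 on the training split reduces
   the space; then elastic-net-penalized logistic regression (mixing
   parameter alpha = 0.5) is refitted on 1,000 class-stratified bootstrap
   resamples, tallying how often each feature's coefficient is nonzero.
   Features selected in at least 25% of rounds survive.
4. **Classifier assembly.** A random forest is grown on the surviving
   features; features in the lowest 10% of mean-decrease-Gini importance
   are dropped (at least one per round) and the 10-fold cross-validated
   mean squared error — the Brier score of out-of-fold case probabilities
   against the 0/1 label — is recorded at every size down to one feature.
   The chosen size minimizes that error, ties broken toward the smaller
   set: the knee of the error curve. `mtry` and `nodesize` are then tuned
   by an accuracy-maximizing grid search over repeated 1/3-train, 2/3-test
   splits, and the final probability forest is refit on the full training
   split. Its score is the fraction of trees voting "case", in [0, 1].
5. **Evaluation** on the withheld validation split: Mann–Whitney AUC with a
   class-stratified percentile-bootstrap CI, univariable and multivariable
   logistic odds ratios (Wald intervals), 2×2 odds ratios, Kaplan–Meier
   curves with log-rank tests among cases split at the 0.5 risk threshold,
   a Gleason-by-risk reclassification table, and reverse-Kaplan–Meier
   median potential follow-up. A score above 0.5 is "high risk"; exactly
   0.5 is low.

## The synthetic cohort generator

Real exon-array cohorts of this design are large and access-controlled, so
the package ships a generator, `simulateCohort()`, whose defaults encode
the cohort structure the pipeline targets: 545 samples (192 metastasis
cases, 184 PSA controls, 169 NED controls), 19 hybridization batches, a
359/545 training fraction, and one technical-replicate profile per batch.

Its statistical structure is deliberately the *minimal* structure the
analysis assumes:

- **Expression.** Log2-scale values with per-feature baselines drawn from
  N(7, 1.5), i.i.d. Gaussian noise (`noise_sd`, default 1 log2 unit), and
  additive per-(batch, feature) Gaussian offsets (`batch_sd`, default 0.5).
  Additive offsets are the simplest batch structure that PCA-based
  correction can provably attack; location/scale or nonlinear batch
  distortions are out of scope.
- **Signal.** `n_informative` features (default 30 at the 5,000-feature
  desk scale) are shifted by `effect_size` (default 1.0 log2 units, random
  sign) in cases only. NED and PSA controls draw from the *same*
  expression distribution by construction, mirroring the observation that
  essentially no features separate those two groups; they differ only in
  clinical fields (BCR, salvage-therapy eligibility).
- **Clinical covariates.** Gleason category, SVI, ECE, margin and node
  status and treatment flags are sampled at case/control rates patterned
  on the real cohort's characteristics table, so P(GS ≥ 8 | case) >
  P(GS ≥ 8 | control) and similarly for the stage variables. Pre-operative
  PSA is log-normal with ~3% missing, exercising the imputation path.
- **Survival.** Times from BCR are exponential with the rate scaled by an
  individual's *planted-signal burden* (the mean signed deviation of their
  informative-feature expression), so higher burden implies shorter time
  to prostate-cancer death; censoring is uniform on 5–20 years; a
  prostate-cancer death always implies an overall-survival event, and ~10%
  of PSA controls metastasize late (outside the 5-year case window). The
  generative survival model is a package choice — the study design only
  fixes the endpoint definitions.
- **Technical replicates.** Each replicate is a fixed ground-truth profile
  plus technical noise (SD 0.2 log2 units); a `tech_unreliable_frac`
  (default 10%) of features get a 10× inflated SD so that, with 19
  replicates, they land in the top variance decile with high probability.

Everything is a pure function of the configuration: the same `SimConfig`
yields bit-identical cohorts and the caller's RNG state is untouched.

What passing tests on these cohorts *does* show: the selection stages
recover planted markers, batch correction removes additive batch structure
without eating case-control signal, the score and risk contracts hold, and
the evaluation statistics agree with hand-computable oracles. What it does
*not* show: performance on real tumor expression data, where effects are
correlated across features, batch effects are not purely additive, and
noise is heavier-tailed. Headline AUCs from the real 545-patient cohort
(GC 0.75 in validation) are not reproducible at desk scale and are not
asserted anywhere in the package.

## Numerical and design choices

Several points are open in the procedure as usually described; the package
fixes them as follows.

- **Batch association statistic.** "ANOVA against batch" is scored as the
  one-way R², which is scale-free and monotone in the F statistic.
- **PCA orientation.** Components are sample-space directions (right
  singular vectors of the feature-centered matrix) — the objects that batch
  labels index. Removal subtracts the rank-one reconstruction of the
  flagged components; total variance drops by exactly their variance
  (tested to 1e-8 relative tolerance).
- **Correction scope.** The correction is fitted on all samples by default
  (the convention when a single matrix is corrected before splitting);
  `batch_fit = "train"` refits on the training split only and projects the
  remaining samples off the learned directions, for stricter validation
  hygiene.
- **Variance-filter ties** are all removed (every feature at or above the
  cutoff quantile).
- **Penalty strength** inside each bootstrap resample is chosen by 5-fold
  cross-validated deviance at fixed alpha (`lambda.min`), re-tuned per
  resample by default; `tune_per_resample = FALSE` tunes once globally.
  Selection means an exactly zero coefficient in the solver's active set —
  no magnitude thresholds.
- **Bootstrap resamples** are size-n with replacement, stratified by class,
  which preserves class balance and avoids degenerate one-class fits.
  Rounds where the solver fails are skipped and counted, with a warning
  above 1% skipped.
- **Elimination-curve MSE** is the out-of-fold Brier score; "MSE" of a
  classification forest is otherwise ambiguous. The knee is the curve's
  argmin with a smaller-size tie-break. When 10% of the current set is
  below one feature, one feature is dropped.
- **Tuning grid defaults**: mtry over {1, ceil(sqrt(p)), ceil(p/3),
  ceil(p/2), p} clipped to [1, p]; nodesize over {1, 2, 5, 10, 20}. Ties
  break toward smaller nodesize, then smaller mtry, making the choice
  deterministic. The final forest is refit on the full training split with
  the tuned parameters (rather than keeping a tuning-time ensemble).
- **Clinical encoding**: Gleason dichotomized at ≥ 8, pPSA
  log2-transformed, stage variables as binaries. Missing pPSA is
  median-imputed with a missingness indicator; when the indicator itself
  separates the outcome (a near-certainty when only a handful of values
  are missing) it is dropped with a warning while the imputation is kept.
  Complete separation by a substantive covariate is an error naming the
  covariate.
- **Odds ratios**: Wald intervals on the log scale (z = 1.959964); a zero
  cell triggers the Haldane–Anscombe +0.5 correction, flagged in the
  result; a fully zero margin is an error. Two-sided p-values are Wald.
- **AUC CI**: class-stratified percentile bootstrap (2,000 replicates by
  default). The point estimate is the Mann–Whitney concordance with ties
  counting one half.
- **Log-rank**: unweighted two-group chi-square with 1 d.f. The KM median
  is the first time survival reaches 0.5 or below.
- **Seeding.** All randomness flows from one master seed through named
  integer substreams (bootstraps, folds, forests, splits), and every
  seeded function restores the caller's RNG state.

## Problem sizes used by the test-suite and demo runs

The package's own verification runs at desk scale, chosen so the complete
suite and the demonstration pipeline execute comfortably on a single CPU:
simulated cohorts of 600–5,000 features and 120–300 samples, 40–100
bootstrap rounds for stability selection, 100–300 trees per forest, and
reduced tuning splits. These sizes are stated here as the package's chosen
study conditions for its synthetic experiments; the algorithmic defaults
(1,000 bootstraps, 1,000 trees, 10-fold CV) remain the production settings
a user inherits unless overridden.

## Known limitations

- With many diffuse batches (the 19-batch default), removing two principal
  components reduces but cannot eliminate batch-associated variance — batch
  structure spans up to 18 sample-space dimensions. The two-component
  convention is kept because it is the procedure being implemented; the
  `n_remove` argument exposes the dial.
- The generator's i.i.d. noise and independent planted effects make
  selection easier than on real arrays with correlated features; recovery
  rates on synthetic cohorts are upper bounds, not forecasts.
- Forest scores are deterministic given the seed, but only statistically —
  not bitwise — invariant to feature reordering at training time, because
  variable sampling is index-based. Scoring a *fitted* model is exactly
  invariant to input row order.
- The nested case-control design means absolute risks are not estimable;
  scores are ranking devices, and no calibration to metastasis
  probabilities is attempted.

## A minimal run

```{r demo, eval = FALSE}
cfg <- pipelineConfig(
  simulation = simConfig(n_features = 2000, n_informative = 25,
                         n_cases = 80, n_ned = 40, n_psa = 40,
                         n_batches = 8, n_tech_reps = 8, seed = 1),
  selection = selectionConfig(n_boot = 100),
  forest = forestConfig(n_trees = 300, tune_boot = 20),
  master_seed = 1)
report <- runPipeline(cfg)
report
```
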