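# metGC

Development and validation of genomic classifiers of early prostate-cancer
metastasis from case-control expression data.

## The problem

After radical prostatectomy, biochemical recurrence (a rising PSA) is a
sensitive but unspecific warning: most men who recur never metastasize, yet
some progress to clinical metastasis within five years and die of prostate
cancer. Clinicopathologic variables — Gleason score, seminal vesicle
invasion, extra-capsular extension, margin and node status — rank risk only
coarsely. `metGC` implements, as reusable and tested R functions, the full
procedure for building an expression-based **genomic classifier (GC)** of
early metastasis and benchmarking it against a **clinical-only logistic
model (CC)** and their **integrated combination (GCC)**:

1. **Feature reliability filtering** — drop features with < 4 probes or
   cross-hybridization flags, then the top 10% of features by variance
   across technical-replicate control profiles.
2. **Batch-effect removal** — decompose the centered matrix into principal
   components over samples; score each of the first 10 against batch by
   one-way ANOVA R²; subtract the two most batch-associated components.
3. **Two-stage feature selection** — per-feature Welch t-test (p < 0.01)
   on the training split, then elastic-net logistic regression (α = 0.5)
   refitted on 1,000 class-stratified bootstrap resamples; features with a
   nonzero coefficient in ≥ 25% of rounds survive.
4. **Classifier assembly** — random forest with backward elimination of
   the lowest-10% mean-decrease-Gini features, choosing the feature-set
   size at the knee (argmin) of the 10-fold cross-validated Brier error
   curve; `mtry`/`nodesize` tuned by an accuracy-maximizing grid search
   over repeated 1/3–2/3 splits. The GC score is the fraction of trees
   voting "case", in [0, 1]; scores > 0.5 are high risk.
5. **Evaluation** on a withheld validation split — Mann–Whitney AUC with
   stratified-bootstrap CIs, univariable/multivariable logistic odds
   ratios and 2×2 Wald odds ratios, Kaplan–Meier curves with log-rank
   tests, Gleason-by-risk reclassification tables, and reverse
   Kaplan–Meier median follow-up.

A seeded synthetic-cohort generator (`simulateCohort()`) reproduces the
statistical structure this analysis assumes — planted case-vs-control
expression shifts, additive per-(batch, feature) offsets, clinical
covariates correlated with case status, burden-dependent survival times,
and technical-replicate profiles with a fraction of unreliable features —
so every stage is testable end to end at desk scale.

## A worked example

```r
library(metGC)
cfg <- pipelineConfig(
  simulation = simConfig(n_features = 2000, n_informative = 25,
                         n_cases = 80, n_ned = 40, n_psa = 40,
                         n_batches = 8, n_tech_reps = 8, seed = 1),
  selection = selectionConfig(n_boot = 100),
  forest = forestConfig(n_trees = 300, tune_boot = 20),
  master_seed = 1)
report <- runPipeline(cfg)
#> loaded cohort: 2000 features x 160 samples
#> reliability filters: 2000 -> 1812 -> 1630 features
#> batch correction removed PCs 1, 2 (max batch R2 0.98)
#> t-filter: 1630 -> 40 features
#> stability selection: 40 -> 39 features
#> backward elimination: 39 -> 15 markers
#> tuned forest: mtry 1, nodesize 5
report
#> EvaluationReport
#>   feature funnel: 2000 -> 1630 -> 40 -> 39 -> 15
#>   validation AUC GC:  0.968 (0.909-1.000)
#>   validation AUC CC:  0.726 (0.579-0.861)
#>   validation AUC GCC: 0.967 (0.901-1.000)
#>   validation AUC GS:  0.689 (0.551-0.820)
#>   median follow-up (reverse KM): 13.10 years
```

Reading the output: the *feature funnel* traces the pipeline's reductions
(input features → reliability-filtered → t-filter survivors →
stability-selected → final markers). The validation AUCs compare the three
classifiers and Gleason score alone on samples no fitting stage ever saw;
here the genomic classifier recovers the planted signal (AUC 0.97) and
clearly outperforms the clinical model (0.73), while the integrated model
tracks the genomic one. Scores, odds-ratio tables, KM results and the
reclassification table live in the returned `EvaluationReport`
(`report@scores`, `report@orUVA`, `report@km`, `report@reclass`).

The evaluation statistics are also usable directly, e.g. the Wald odds
ratio of a 2×2 table of high/low-risk calls by case status:

```r
oddsRatio2x2(42, 28, 21, 95)
#> OR 6.79 (95% CI 3.46-13.29), p = 2.38e-08 [wald_2x2]
```

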