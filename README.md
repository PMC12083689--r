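# survdistill

Interpretable prognostic modelling for right-censored clinical cohorts:
`survdistill` fits a random survival forest, *distills* the forest's split
rules for each continuous predictor into a small set of clinically usable
cutoffs, and rebuilds the model as a shallow decision tree whose leaves are
merged into ordered risk groups — the kind of rule list ("KPS low and
SIRI ≥ 3.5 → highest-risk group") that can be applied at the point of care.

The motivating biomarker is the **systemic inflammatory response index**

    SIRI = (absolute neutrophil count × absolute monocyte count) / absolute lymphocyte count

from a pre-treatment complete blood count, modelled together with
performance status, body-mass index and smoking status in head-and-neck
radiotherapy cohorts. The package also provides the companion
cross-sectional analysis linking SIRI to patient-reported **financial
toxicity** (FT, ordinal 0–3): a Jonckheere–Terpstra ordered-trend test and
a multiple linear regression of log2(SIRI) on the dichotomized FT level
(0–1 = FT-Low, 2–3 = FT-High) plus confounders.

## Method

1. **Forest.** A random survival forest (1000 bootstrap trees, log-rank
   splitting, minimum terminal size 15; `ranger` engine) is fitted on the
   training 70% of an event-stratified split. Each subject's risk is
   summarized by the ensemble *mortality score*: the sum of the ensemble
   Nelson–Aalen cumulative hazard over the unique training event times.
2. **Cutoff distillation.** For a continuous predictor, every split
   threshold the forest used is extracted. The Gaussian kernel density of
   these thresholds is compared with the kernel density of the training
   values on a shared 512-point grid; *local maxima of the difference* mark
   values where the forest splits more often than the data distribution
   alone explains. Candidate cutoffs that would create a group holding
   < 10% of the training subjects are excluded, weakest first.
3. **Risk tree.** Continuous predictors are discretized at the distilled
   cutoffs and a depth-≤3 decision tree with minimum leaf size 40 is grown
   by exhaustive greedy log-rank splitting over category subsets. Leaves
   are ordered by mean mortality score and adjacent leaves whose survival
   curves are statistically indistinguishable (pairwise log-rank p > 0.05,
   or down to a target count) are merged into ordered risk groups.
4. **Validation.** On the held-out 30%: Harrell's C-index, time-dependent
   IPCW AUC, per-group Kaplan–Meier curves, global and pairwise log-rank
   tests with Holm–Bonferroni correction, pairwise univariable Cox hazard
   ratios (Efron ties), and a binary high/low stratification at the 75th
   percentile of the training mortality scores.

A seeded synthetic-cohort generator (log-normal SIRI, categorical
KPS/smoking structure, proportional-hazards event times with *threshold*
covariate effects at plantable cutoffs, exponential + administrative
censoring, ordinal FT labels with a monotone log2(SIRI) shift) makes the
whole pipeline testable end-to-end without patient data.

## Worked example

```r
library(survdistill)

cfg <- pipeline_config(master_seed = 11)   # 600 subjects, planted cutoffs
report <- run_pipeline(cfg)
report
```

```
survdistill run report
  cohort: n = 600 (train 420 / test 180)
  C-index: train (OOB) 0.591, test 0.597
  time-dependent AUC: month_12=0.667, month_24=0.641, month_36=0.632, month_48=0.643
  cutoffs[siri]: 1.427, 2.254, 4.007
  cutoffs[bmi]: 20.45, 24.49, 27.48, 32.5
  risk groups: 3 (test-set log-rank p = 0.00128)
  FT trend (Jonckheere, two-sided) p = 4e-05
```

The default configuration plants a hazard step at SIRI = 3.5 (hazard
ratio 2.5), an increased hazard for low performance status, and a milder
step below BMI = 25. In the run above the strongest distilled SIRI cutoff
lands at 4.0 (truth 3.5) and one BMI cutoff at 24.5 (truth 25), alongside
weaker spurious candidates — single-run cutoffs are noisy, which is why the
acceptance script quantifies recovery over 20 replicate cohorts. The
held-out test set shows a C-index of 0.60, three ordered risk groups
separated at p ≈ 0.001, and the planted monotone FT→SIRI trend detected at
p ≈ 4e−5. `risk_group_rules(report$risk_model)` prints one rule per leaf,
e.g. `siri not in {<1.43, [1.43,2.25), [2.25,4.01)} -> Group 3` (i.e.
SIRI ≥ 4.0 is the highest-risk group).

Individual stages are exported on their own: `generate_covariates()` /
`assign_survival()` / `generate_ft_labels()` (simulation), `compute_siri()`
/ `categorize_bmi()` / `categorize_ft()` (features), `fit_forest()` /
`predict_mortality()` / `concordance_index()` / `time_dependent_auc()` /
`permutation_vimp()` (forest), `distill_cutoffs()` (cutoffs),
`grow_risk_tree()` / `merge_leaves()` / `assign_risk_group()` (risk tree),
`kaplan_meier()` / `logrank_test()` / `cox_univariable()` /
`holm_bonferroni()` (validation), `jonckheere_test()` / `ols_regression()`
(FT association). Artifacts (cohort CSV, cutoff-set JSON, risk-model JSON,
run-report JSON, YAML configs) are written by `run_pipeline(output_dir=)`.

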