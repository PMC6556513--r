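# trajresponse

Detecting an imaging response to treatment from longitudinal, routinely
acquired imaging features — and measuring how much statistical power a
high-dimensional readout buys over conventional low-dimensional summaries.

## The problem

In diseases with anatomically distributed pathology, such as multiple
sclerosis, the effect of a disease-modifying treatment on brain imaging is
spread across many regions. Conventional trial endpoints compress imaging to
a handful of global numbers — total brain volume, lesion count, total lesion
volume — and may miss a response that is obvious when many regional
measurements are considered jointly. `trajresponse` implements a complete,
tested pipeline for quantifying that difference on tabular, per-scan imaging
features (regional grey-matter volumes and regional disconnection estimates,
plus the global aggregates), for biostatisticians and imaging researchers
who want to evaluate high- vs low-dimensional response detection or to power
a trial around it.

## The method

For each patient and each feature, the scans before treatment start (t < 0)
and after it (t > 0) are treated as two separate time series. Each series
with at least two scans is summarised by its ordinary least-squares slope
β, then dichotomised to a *trajectory* sign(β) ∈ {−1, 0, +1}, deliberately
discarding magnitude so that heterogeneous scan timing cannot bias the
model. Homologous left/right regional trajectories are collapsed by
summation to a net trajectory in {−2, …, +2}. The classification task is:
given a patient-period's trajectory vector, was it observed before (class 0)
or after (class 1) treatment start?

Around that core the package provides:

- **Deconfounding** — volumetric features are normalised by total
  intracranial volume, then ten acquisition and clinical covariates (age,
  gender, scanner manufacturer, field strength, disease duration, EDSS,
  T1/FLAIR slice thickness and voxel resolution) are regressed out of every
  feature with Bayesian ridge regression (evidence-maximised penalty).
  Removal is verified *adversarially*: classifiers are trained to predict
  each dichotomised confounder from the residualised features, and must fail
  (`verify_deconfounding()`).
- **Subject-constrained bootstrap cross-validation** — 500 (by default)
  random 80/20 splits drawn at the patient level, so both trajectory vectors
  of a patient with pre- and post-treatment data always land on the same
  side; models (RBF-kernel SVM with C = 10, γ = 1/p; extremely randomised
  trees with 100 trees, Mf = √p; both with balanced class weights) are
  scored on the held-out patients only (`bootstrap_cv()`).
- **Greedy forward feature selection** by mean out-of-fold AUC
  (`greedy_forward_selection()`), and an **AUC-weighted ensemble** of the
  regional-volume and regional-disconnection models (`ensemble_cv()`).
- **Permutation null models** — each feature's values are shuffled within
  patient before slopes are computed, destroying temporal signal while
  preserving scan timing (`permute_null()`).
- **Simulated randomised controlled trials** — subsets of N patients are
  drawn repeatedly; each trial tests the association between the
  classifier's out-of-fold consensus prediction and the true period with
  Fisher's exact test, yielding mean odds-ratio and achieved-power curves
  against enrolment size (`simulate_rcts()`).
- **A synthetic cohort generator** (`generate_cohort()`) emulating the
  statistical structure of such feature tables: 16 / 60 / 27 patients with
  pre-only / post-only / both periods, 72 homologous region pairs (288
  regional variables per scan), regional atrophy and rising disconnection
  before treatment with stabilisation after, linear covariate confounds, and
  realistic measurement noise. Ground truth is retained for
  parameter-recovery tests.

## Worked example

```r
library(trajresponse)
library(dplyr)

cohort <- generate_cohort(cohort_config(seed = 11))
clean  <- deconfound_cohort(cohort)        # TIV-normalise + residualise
traj   <- build_trajectory_dataset(clean)  # 130 patient-period vectors
sets   <- predictor_sets(traj)

fit_low  <- bootstrap_cv(traj, sets$low_dimensional,
                         classifier_spec("ert"), n_iter = 100, seed = 31)
fit_vol  <- bootstrap_cv(traj, sets$regional_volume,
                         classifier_spec("ert"), n_iter = 100, seed = 31)
fit_disc <- bootstrap_cv(traj, sets$regional_disconnection,
                         classifier_spec("ert"), n_iter = 100, seed = 31)
fit_ens  <- ensemble_cv(fit_vol, fit_disc)

bind_rows(glance(fit_low), glance(fit_vol), glance(fit_disc), glance(fit_ens))
#> # A tibble: 4 × 7
#>   classifier    n_features n_iter n_vectors auc_mean auc_ci_low auc_ci_high
#>   <chr>              <int>  <dbl>     <int>    <dbl>      <dbl>       <dbl>
#> 1 ert                    3    100       130    0.696      0.676       0.716
#> 2 ert                   72    100       130    0.836      0.820       0.852
#> 3 ert                   72    100       130    0.803      0.783       0.822
#> 4 ensemble(ert)        144    100       130    0.905      0.891       0.919
```

The three-variable low-dimensional model detects the treatment period with a
mean out-of-fold AUC of 0.70; the two regional models reach 0.80–0.84; their
AUC-weighted ensemble reaches 0.90, a margin far beyond the bootstrap
confidence intervals — the dimensionality effect the package exists to
measure. Feeding the ensemble's consensus predictions into simulated trials
turns that margin into statistical efficiency:

```r
rct <- simulate_rcts(
  consensus_predictions(fit_ens) |> select(patient_id, label, predicted),
  n_grid = c(25, 50, 103), n_rep = 200, alpha = 0.01, seed = 61)
tidy(rct)
#> # A tibble: 3 × 7
#>       n or_mean or_ci_low or_ci_high power power_ci_low power_ci_high
#>   <dbl>   <dbl>     <dbl>      <dbl> <dbl>        <dbl>         <dbl>
#> 1    25    52.5      47.9       57.1 0.845        0.795         0.895
#> 2    50    97.5      93.0      102.  1            1             1
#> 3   103   183.      183.       183.  1                1             1
```

At 25 enrolled patients a trial built on the ensemble already rejects the
null in 84% of simulations at α = 0.01; by 50 patients power is complete.
`autoplot()` methods draw the metric distributions, selection traces and
power/odds-ratio curves; `run_experiment()` drives the whole pipeline
(including permutation nulls and deconfounding verification) and
`write_experiment()` exports the result tables as CSV/JSON.

## Package layout

| Area | Functions |
|---|---|
| Synthetic cohorts | `cohort_config()`, `generate_cohort()`, `read_cohort()`, `write_cohort()` |
| Trajectory features | `split_periods()`, `fit_slope()`, `slope_to_trajectory()`, `collapse_hemispheres()`, `build_trajectory_dataset()` |
| Deconfounding | `normalize_by_tiv()`, `bayesian_ridge()`, `residualize_features()`, `binarize_confounder()`, `verify_deconfounding()` |
| Models | `classifier_spec()`, `make_classifier()`, `bootstrap_cv()`, `greedy_forward_selection()`, `ensemble_cv()`, `permute_null()` |
| Evaluation | `roc_auc()`, `confusion_metrics()`, `aggregate_bootstrap()`, `ks_compare()` |
| Trials | `consensus_predictions()`, `odds_ratio()`, `fisher_exact_p()`, `simulate_rcts()` |
| Driver | `experiment_config()`, `run_experiment()`, `write_experiment()` |

See `vignettes/imaging-response-detection.Rmd` for the full methodological
account, including the generator's design rationale and known limitations.
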