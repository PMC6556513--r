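---
title: "Detecting imaging response to treatment: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting imaging response to treatment: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its methods: the model and its
assumptions, the parameters that matter, what the synthetic cohort generator
does and does not emulate, the numerical choices, and the limitations a user
should know about before trusting a result.

## The model

The unit of analysis is the *patient-period*: the set of a patient's scans
falling strictly before (class 0) or strictly after (class 1) the start of
treatment, with treatment start at time zero. A scan at exactly t = 0 is
excluded with a warning — it belongs to neither change regime. For every
imaging feature and every period holding at least two scans, the feature is
regressed on scan time by ordinary least squares and the slope is
dichotomised to its sign: +1 rising, −1 falling, 0 only under exact floating
equality. The zero class exists for ordinal or bounded features that can
genuinely produce a flat fitted line; a continuous feature hits it with
probability zero, so no tolerance band is applied. Homologous left/right
regional trajectories are summed into a net trajectory in {−2…+2}; global
aggregates (total brain volume, total lesion volume, lesion count) remain
singletons in {−1, 0, +1}.

Two assumptions are baked in. First, within a period, change is adequately
summarised by a straight line — the trajectory keeps only its direction, so
curvature and magnitude are deliberately discarded; this buys robustness to
heterogeneous scan timing at the cost of sensitivity (no weighting by slope
reliability is attempted). Second, treatment effects are not lateralised, so
summing hemispheres loses little and halves the feature count.

Classification of pre- vs post-treatment trajectory vectors uses two fixed
model families: a support vector machine with Gaussian radial basis kernel
(penalty C = 10, kernel coefficient γ = 1/p for p features) and extremely
randomised trees (Gini splits, 100 trees, Mf = ⌊√p⌋ features per split,
one random cut per candidate feature), both with class weights inversely
proportional to training-class frequencies. These are deliberately fixed
defaults, not tuned quantities. Continuous scores come from the fraction of
trees voting class 1, and from the SVM decision value mapped through a
logistic function; hard decisions threshold at 0.5 with ties going to class
1. ROC analysis needs continuous scores and both conventions are
monotone-invariant for AUC.

## Subject-constrained evaluation

All performance estimates are out-of-fold: `bootstrap_cv()` draws, per
iteration, a random 80/20 partition *of patients* (never of vectors), fits
on the training patients' vectors and scores only the held-out patients'
vectors. Allocating whole patients guarantees that the two vectors of a
both-period patient never straddle the split — otherwise a model could
recognise the patient rather than the treatment period. Splits are random
partitions without replacement: sampling training patients with replacement
would break the full-holdout construction. Splits whose training side lacks
a class are redrawn (25 attempts, then error); iterations whose held-out set
is single-class record AUC, sensitivity and specificity as missing and drop
out of those metrics' aggregation only. Metrics aggregate as mean ± 1.96
standard errors across iterations. An optional `balance = "subsample"` mode
subsamples majority-class training vectors to the minority count.

The ensemble of the regional-volume and regional-disconnection models is a
weighted average of their scores with weights proportional to the two mean
AUCs; `ensemble_cv()` recombines two runs that used the same seed (hence
identical splits) and recomputes all metrics per iteration, so the ensemble
is evaluated under exactly the same out-of-fold discipline as its
components.

Greedy forward selection starts from the single feature with the highest
mean out-of-fold AUC and adds, at each step, the candidate maximising the
mean AUC of the augmented set, evaluating every candidate on identical
splits (a paired comparison). The chosen model size is the argmax of the
cumulative curve, ties resolved toward the smaller model; selection runs
once and its result is reused, never re-run inside evaluation.

## Deconfounding and its adversarial verification

Volumetric features are divided by each scan's total intracranial volume,
then every feature is residualised against ten covariates: age, gender,
scanner manufacturer, field strength, disease duration, EDSS (both taken at
treatment start and constant within patient), and T1/FLAIR slice thickness
and voxel resolution. Continuous covariates are standardised; categorical
ones one-hot encoded with the reference level dropped. The regression is a
Bayesian ridge with both precisions estimated by fixed-point evidence
maximisation — a proper shrinkage prior whose penalty adapts per feature;
with the penalty pinned near zero it reproduces ordinary least squares
exactly, which is how the implementation is tested. Residuals are returned
plus the feature's grand mean, keeping features on their original scale.
Residualisation precedes slope fitting, and is fitted on all scans.

Verification is adversarial: each covariate is dichotomised (continuous:
below the sample mean; manufacturer: modal category vs rest; field strength:
1.5 T vs 3 T; slice thickness: < 6 mm; gender as is) and classifiers try to
predict it from the per-scan residualised feature vector under the same
subject-constrained bootstrap. Success means failure to predict.

One structural subtlety deserves honesty. Residualisation enforces *exact
in-sample* orthogonality between each feature and the covariate encodings.
For verification targets that coincide with a design column (gender, field
strength, the modal-manufacturer split), the full-sample class difference of
every feature is then pinned to zero, which makes the training-fold and
held-out-fold differences *anti-correlated*: a classifier that learns the
training fold's residual direction is systematically wrong on the held-out
fold, and held-out AUC lands below 0.5 rather than at it. The effect grows
with the number of effectively independent feature dimensions and shrinks
with sample size; it is a property of verifying on the same sample the
regression was fitted on, not a bug. The package therefore frames successful
deconfounding the way a practitioner should read it: after residualisation
no confounder is predictable *better than chance*, while before
residualisation the scanner covariates are. For the same reason the
permutation-null check asserts a chance *envelope* rather than exact CI
coverage of 0.5: a single permutation of 130 vectors retains chance
association of order 1/√130, and mean-±-SE intervals across bootstrap
iterations quantify split noise only, not permutation noise; the null check
averages over several permutations.

## Simulated randomised controlled trials

Each vector's out-of-fold scores are averaged into a consensus prediction
(threshold 0.5, ties to class 1; every vector must have been held out at
least once, which is guaranteed for practical iteration counts). A simulated
trial of size N samples N patients without replacement — an RCT enrols
distinct patients — pools all their vectors (a both-period patient
contributes both) into a predicted × true 2×2 table, and computes the sample
odds ratio and the two-sided Fisher exact p-value. Per N, the package
reports the mean odds ratio with a standard-error CI and the achieved power:
the fraction of repetitions with p < α (default α = 0.01), with a
normal-approximation binomial CI. Power is estimated empirically by
rejection counting rather than through an analytic power calculator: same
estimand, no opaque external tool. The sample odds ratio uses the
Haldane–Anscombe correction (add 0.5 to every cell when any cell is zero),
which guarantees finiteness but is upward-biased and skewed at small N — so
the *mean* OR across repetitions can legitimately decrease toward the true
OR as N grows for a fixed predictor, even while power rises monotonically.
A table with an empty margin carries no evidence of association and scores
p = 1.

## The synthetic cohort generator

No real patient data ship with the package; `generate_cohort()` produces
feature tables with the statistical structure the analysis assumes, and its
defaults define the reference study conditions.

**Cohort composition.** 16 patients with ≥2 pre-treatment scans only, 60
with ≥2 post-treatment scans only, 27 with both — 103 patients and 130
trajectory-eligible patient-periods, of which 43 (33.1%) are class 0. Scans
per period are uniform on 2–5; pre-treatment times uniform on (−3, −0.1]
years, post-treatment on [0.1, 4), so no scan sits at exactly t = 0.

**Covariates.** Age ~ N(38, 10) clipped to 20–70 and advancing with scan
time; gender 44M:80F; disease duration ~ N(6.3, 2.2) advancing with time;
EDSS ~ N(4.8, 1.7) constant within patient; three scanner manufacturers
(50/30/20%), field strength 1.5/3 T (60/40%), slice thicknesses in
{1, 3, 6} mm and voxel sizes uniform on 0.9–1.3 mm, all resampled per scan
because routine patients change scanners.

**Features.** Each of 72 region pairs has a cohort-level typical volume
(4 000–12 000 mm³) scaled per patient by a shared anatomy factor
proportional to the patient's TIV (~N(1.45 × 10⁶, 9 × 10⁴) mm³), so TIV
normalisation removes patient scale — which is its purpose. An affected
subset of pairs (30% by default) carries patient-specific slopes: volume
−30 mm³/yr (sd 10) pre-treatment and +4 mm³/yr (sd 5) after; disconnection
+0.005/yr (sd 0.002) pre and ≈0 after, clipped to [0, 1]. Unaffected
regions have zero structural slope. Measurement noise is predominantly a
*shared* per-scan shift (sd 50 mm³ on volumes, scaled by 2 × 10⁻⁴ for
disconnection) with a smaller independent per-region component (sd
`noise_sd/5` by default, configurable via `idio_noise_sd`): parcellation
errors from scanner, positioning and segmentation move all regions of a
scan coherently. Lesion count is a monotone latent process (new lesions
Poisson at 2/yr before treatment, 0.05/yr after) observed with integer
miscount noise (sd 3); lesion volume is proportional to the latent count
with lognormal noise. Total brain volume is the sum of regional volumes.
Covariates add linear offsets to every regional feature (largest: field
strength, ~2.4 shared-noise sd), giving the deconfounding verification a
real effect to remove.

**Why these effect sizes.** With per-region signal near one noise-sd per
year, every regional sign becomes nearly deterministic, all regional models
saturate near AUC 1 and the dimensionality comparison degenerates. The
defaults instead put each region in the weakly-informative regime — a
single regional trajectory separates the classes only modestly — so that
high-dimensional performance must come from pooling many regions while the
global aggregates stay weak. That is the phenomenon the package exists to
exhibit, and the regime in which the model-comparison, null, verification
and power properties in the test suite are asserted. The strong-effect
configuration used to validate feature-selection recovery (12 pairs, 4
affected, idiosyncratic noise dominant) raises per-region information and
makes regional evidence approximately independent, because greedy selection
can only keep finding affected regions if each new one adds information.

**What is not emulated.** No image-level processing (parcellation,
segmentation, tractography) — only their tabular outputs; no non-linear or
interaction confounds; no pseudoatrophy (transient early post-treatment
volume loss); no lateralised treatment effects; no missing covariates; no
spatial correlation structure between neighbouring regions beyond the
shared-scan factor; no patients lacking two scans in every available
period. Passing tests on these cohorts therefore demonstrates that the
*pipeline* behaves correctly under its own assumptions, not that any real
cohort satisfies those assumptions.

## Numerical choices and degenerate inputs

- Slope fitting requires ≥2 scans and non-degenerate times; single-scan
  periods are skipped, never imputed.
- Exact-zero slopes map to trajectory 0 under exact equality only.
- The ridge design drops categorical reference levels and standardises
  continuous columns; a constant column standardises to zeros.
- Evidence maximisation iterates at most 100 times to coefficient tolerance
  1e−8, with precisions floored at 1e−10 to avoid division blow-ups.
- `tidy()` reports NA for a metric defined in fewer than two iterations
  rather than failing the whole run.
- Bootstrap CI = mean ± 1.96 sd/√n across iterations; constant metric
  vectors give a zero-width interval.
- Fisher's test and the KS test delegate to the standard exact/asymptotic
  implementations (`stats::fisher.test`, `stats::ks.test`, the latter exact
  for small samples without ties).
- All randomness flows from explicit integer seeds; regeneration is
  bit-identical, and `ensemble_cv()` refuses runs whose out-of-fold ledgers
  do not align exactly.

## Desk-scale problem sizes

The package's reference runs use 100 bootstrap iterations (against 500 for
a full analysis) and, for selection-recovery checks, the reduced
strong-effect configuration above; these sizes were chosen so that a
complete pipeline run is an interactive-scale computation while every
asserted margin (ensemble vs low-dimensional, before vs after
deconfounding, power growth with N) remains several CI-widths wide.

## Known limitations

- Trajectories ignore slope reliability; patients with two close-together
  scans contribute signs as confidently as patients with five scans over
  years.
- The verification anti-correlation described above means held-out
  confounder-prediction AUC is a one-sided check (no residual *usable*
  signal), not an unbiased estimate of 0.5.
- Greedy selection with strongly correlated candidates stops early — the
  cumulative AUC curve plateaus once the shared signal is captured — so
  "features not selected" must not be read as "regions not affected".
- The mean sample odds ratio is a biased effect summary at small N; the
  power curve is the quantity to compare across models.
- Class imbalance (67% post-treatment) is handled by balanced class
  weighting; the subsampling mode exists for sensitivity analysis, not as
  the default.
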