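---
title: "Methods: NMR metabolomics screening for hypertensive pregnancy disorders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: NMR metabolomics screening for hypertensive pregnancy disorders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`nmrscreen` implements a first-trimester screening pipeline that predicts
preeclampsia (PE) and gestational hypertension (GH) from 1D ^1^H NMR
metabolic profiles of maternal urine and serum, and from logistic risk
models that combine a urinary metabolite ratio with maternal
characteristics. This vignette is the package's own account of the
statistical machinery: what each stage assumes, which parameters matter,
and where design decisions were genuinely open.

## The screening problem

In a prospective cohort of women examined at gestational weeks 11–14,
roughly 4% later develop preeclampsia and 3.5% gestational hypertension.
The classification task is therefore severely imbalanced: a useful
screening metric is not raw accuracy but *sensitivity at a fixed 10% false
positive rate*, read off a pooled out-of-sample ROC curve. All pipeline
defaults mirror that design: one-vs-rest outcome labelling inside the full
cohort (for PE prediction the GH women stay among the controls), stratified
resampling so that every block preserves the case:control ratio, and
evaluation by double cross-validation rather than a single split.

## Synthetic cohorts with known ground truth

Raw spectra from a real cohort are not distributed with the package, so
every empirical claim its tests make is exercised on a synthetic cohort
generator (`generate_cohort()`, `synthesize_spectra()`) whose hidden truth
(dilution factors, shift jitter, per-sample concentrations, outcome
mechanism) is recorded and returned.

**Covariates.** Outcome labels are drawn with exact counts
(`round(n * prevalence)`), and maternal covariates per outcome group:
MAP and age are normal with location equal to the reported group medians
(MAP 87.0/92.1/82.7 mmHg for PE/GH/controls; age 26/28/28 years); BMI and
UtAPI are log-normal (medians 24.8/27.1/23.5 kg/m² and 1.75/1.49/1.46).
Scales are derived from the reported interquartile ranges via
`sd = IQR/1.349`, the normal-theory conversion, because only median (IQR)
summaries are available. These are location/scale approximations: real
covariates are skewed in ways a two-parameter law cannot capture.

**Spectra.** A spectrum is a dilution-scaled sum of Lorentzian lines —
the natural NMR line shape — one set per metabolite, plus optional
polynomial baseline and i.i.d. Gaussian noise:

$$
x_i(\delta) \;=\; d_i \sum_m c_{im} \sum_k h_{mk}\,
\frac{\gamma_{mk}^2}{(\delta - (\mu_{mk} + \epsilon_{im}))^2 + \gamma_{mk}^2}
\;+\; e_i(\delta)
$$

with log-normal dilution \(d_i\), log-normal per-sample concentrations
\(c_{im}\) around the library means, and normal per-sample chemical-shift
jitter \(\epsilon_{im}\). Case samples have their mean concentrations
multiplied by an effect map. The urine library holds ~15 metabolites at
textbook chemical shifts (e.g. hippurate aromatic multiplets near
7.5–7.9 ppm plus the CH₂ near 3.97; creatinine 3.05/4.06; citrate AB near
2.55/2.67); the serum library has two broad lipid envelopes (0.9 and
1.3 ppm, line widths ~10× the small molecules) plus sharp glucose,
lactate, alanine, valine, pyruvate and choline signals. Peak positions and
widths are reference-value constants, editable via the library objects —
they are simulation scaffolding, not measured values.

**Effect maps.** The default urine maps lower hippurate, lactate and
proline betaine and raise creatinine, glycine, dimethylamine,
4-deoxythreonic acid, α-hydroxyisobutyrate and histidine in cases; GH
additionally lowers citrate, and otherwise shares the PE multipliers,
reflecting that the two disorders' early metabolic signatures largely
overlap. The source study reports only *directions* of change, never
fold-changes, so the default magnitudes (0.70–1.25) were chosen once to
give the pipeline realistic, detectable-but-imperfect separation; they are
simulation parameters, not estimates, and results on synthetic cohorts
quantify the pipeline's behaviour, not the clinical effect sizes.

**What the generator does not emulate.** Free-induction decays, phase and
baseline artifacts beyond a low-order polynomial, peak overlap from the
hundreds of minor urinary metabolites, pH-dependent shift changes that are
correlated across metabolites (jitter here is independent per metabolite),
and proteinuria or delivery outcomes. Passing recovery tests on this
generator therefore demonstrates correctness of the algorithms under the
stated statistical structure, not clinical performance on real spectra.

## Preprocessing

Urine: `extract_region()` (0.5–9.0 ppm, minus residual water 4.50–5.00 and
urea 5.45–6.05 ppm — the boundaries are conventional residual-signal
windows, configurable) → `interval_align()` → `pqn_normalize()` →
`mean_center()` + `pareto_scale()`. Serum: 0.1–4.2 ppm →
`align_to_peak()` on the alanine doublet at 1.48 ppm →
`unit_area_normalize()` → `mean_center()`. Every stage appends a named
record to the `SpectrumSet` provenance log.

**Alignment.** Interval alignment shifts each sample's segment by the
integer offset (|offset| ≤ `max_shift`) maximizing the inner product with
the reference segment, with edge-value padding; the reference spectrum is
the one with the highest mean Pearson correlation to all others (ties to
the lowest index; zero-variance spectra enter with correlation 0).
Sub-grid interpolation is deliberately omitted: at the linewidths the
generator produces, fractional shifts change nothing testable, and
integer shifts keep the multiset of interior intensities intact — which is
itself a tested invariant. The 245 manually chosen segment boundaries used
on real spectra are not published, so `make_intervals()` tiles the
retained axis into near-equal segments; the tests and acceptance runs use
a tiling matched to their grid resolution (e.g. 120 segments at a
0.005 ppm step), since a segment must span at least `2*max_shift + 1`
points to admit the shift search.

**Probabilistic quotient normalization.** Spectra are first scaled to the
cohort's median total integral, the point-wise median spectrum is the
reference, and each spectrum is divided by the median of its point-wise
quotients over points where the reference exceeds `noise_floor`
(default 0). The returned factor — total-area component times quotient —
is a *relative* dilution estimate anchored so the cohort median factor
is 1: identical spectra give factors of exactly 1 and unchanged output,
and a cohort-wide rescale leaves the factors unchanged. The dilution
recovery test isolates the dilution mechanism (between-sample
concentration variation off, noise and jitter on): with biological
variation active, the recorded dilution factor is confounded with the
sample's consensus concentration shift, and *no* estimator can track it
perfectly — a companion test keeps default biological variation and
verifies the rank correlation stays above 0.9.

**Scaling.** Pareto scaling divides each centered variable by the square
root of its standard deviation — a compromise between unscaled data
(dominated by intense signals) and unit variance (noise inflation);
zero-variance variables pass through unscaled with a warning.

## PLS-DA, VIP and variable selection

`pls_fit()` is PLS1 NIPALS on 0/1-coded labels: weights proportional to
the covariance of the deflated predictors with the deflated response,
unit-normalized; both blocks deflated per component; coefficients
assembled as \(W (P^\top W)^{-1} q\). Predictors are mean-centered inside
the fit (never scaled there — spectral scaling is a preprocessing
decision), and prediction applies the training center only. The y coding
and deflation scheme are not dictated by the methods the pipeline
reimplements, so they are documented defaults: with A components equal to
the predictor rank, predictions provably coincide with least squares, and
a one-component model ranks variables exactly like absolute univariate
correlation — both are tested identities. Class decisions use ROC-derived
cutoffs downstream, not a fixed 0.5, matching evaluation at "the best
cutoff" of the ROC curve.

VIP scores follow the standard definition with
\(SS_a = q_a^2\, t_a^\top t_a\), so \(\sum_j \mathrm{VIP}_j^2 = p\)
exactly; `vip_select()` keeps variables with VIP ≥ 1 after choosing the
component count by 5-fold cross-validated misclassification. Equality at
the threshold is retained because fully symmetric designs (identical
copies of one signal) put every variable at exactly 1.

`cars_select()` implements competitive adaptive reweighted sampling: 50
Monte-Carlo iterations, each fitting PLS on a random 80% sample subset
(the cited method's fraction; the source is silent, so it is
configurable), an exponentially decaying enforced retention schedule
pinned at \(r_1 = 1\) and \(r_{n}\! =\! 2/p\), adaptive reweighted
sampling proportional to |coefficient|, and 5-fold cross-validated RMSE
on the 0/1-coded response as the objective (CARS is defined for
regression residuals); the final set is the minimum-RMSE iteration, ties
to fewer variables. If a sampling draw would collapse the working set
below two variables, the enforced-selection set is used instead; if the
set still collapses, iteration stops and the recorded minimum is used.

Selection runs on the full preprocessed matrix before double CV by
default, mirroring the original sequence (selected variable sets are the
*inputs* to the classification models); this leaks selection information
into the cross-validated estimates, which is why the permutation test
re-runs the *entire* procedure on shuffled labels. A leakage-safe nested
mode — selection inside each outer training fold — is available by
composing the exported functions.

## Double cross-validation, ROC and permutation testing

`double_cv()` holds out a stratified 20% per outer repetition; the
remainder is split 20 times into stratified calibration/test blocks to
choose the component count minimizing mean inner misclassification at the
inner-ROC Youden cutoff (ties to fewer components; the inner split
fraction is unstated in the design this follows, so it defaults to 20%,
mirroring the outer). The model is refitted on the full remainder, the
decision threshold is the Youden cutoff of the remainder's fitted scores,
and the held-out block is scored. Means of per-repetition accuracy,
sensitivity and specificity are primary (matching "mean sensitivity,
specificity and classification accuracy"); pooled held-out scores give
the ROC, AUC and sensitivity at 10% FPR, pooled rather than averaged
because per-repetition ROCs on a handful of cases are unstable. No
statistic used to score a held-out block is computed from that block.

ROC curves use the convention *positive = score > threshold* with
thresholds at midpoints between consecutive distinct scores (infinite end
points). The operating points are exactly the observed ones — no
interpolation — but a selected cutoff sits centrally in the score gap it
splits, which matters when a cutoff chosen on training scores is applied
to held-out samples: a cutoff placed exactly *at* the largest training
control score is exceeded by a held-out control with probability equal to
the held-out share, by rank exchangeability, no matter how separated the
classes are. `sensitivity_at_fpr()` is the maximum TPR over curve points
with FPR at or below the cap (step-function reading); degenerate
constant scores give AUC 0.5 by the tie convention and sensitivity 0 at
any cap below 1.

`permutation_test()` reshuffles the labels and re-runs the supplied
procedure — the full double CV, including selection in nested setups —
and reports \(p = (1 + \#\{e_{perm} \le e_{obs}\})/(n_{perm} + 1)\), with
failed permutations redrawn and counted. The default is 100 permutations;
calibration studies in the tests use 49 to keep the null experiment count
high at fixed cost, which only coarsens the attainable p-value grid.

## Risk models

`metabolite_ratio()` quantifies metabolites as trapezoidal curve areas
over ppm windows on dilution-corrected, unscaled spectra; the default
hippurate aromatic window is 7.45–7.90 ppm and creatinine 2.99–3.10 ppm —
conventional windows, configurable, since the original integration bounds
are unpublished. Ratios to creatinine cancel the dilution factor exactly,
which is why the ratio, not the raw area, is the clinical marker.
`age_highrisk()` flags ages strictly below 20 or strictly above 35.
`logistic_fit()` is maximum-likelihood logistic regression (IRLS via
`stats::glm`) with a likelihood-ratio omnibus test against the
intercept-only model; complete separation (saturated fitted probabilities
that order the classes perfectly) and singular designs are rejected with
diagnostics. `risk_report()` evaluates *apparent* (in-sample) performance,
as the original logistic models do: ROC/AUC via the validation module, a
Hanley–McNeil normal-approximation 95% CI for the AUC (the original
statistics package's method being unstated), and PPV/NPV at the 10%-FPR
operating threshold. The report is deliberately labelled apparent
performance; optimism correction is out of scope. One wording conflict is
resolved here: the risk-table header says sensitivity at 10% "false
discovery rate", while every other use in the design is false *positive*
rate — the package reads it as FPR throughout.

## Numerical choices and degenerate inputs

* Stratified splits take `round(fraction * n_class)` per class, minimum
  one member, drawn uniformly within class; degenerate single-class inner
  test blocks are redrawn (bounded retries).
* NIPALS stops early (with a warning, reducing A) when the residual
  response or score norm falls below 1e-12.
* PCA rejects component counts beyond the numerical rank; the sign
  convention makes the largest-magnitude loading element positive.
* Zero-variance spectra enter reference selection with correlation 0;
  zero-variance variables pass pareto scaling unscaled; flat alignment
  search windows leave the spectrum unshifted — all logged as warnings.
* All randomized operations take an integer `seed` and are
  bit-reproducible given it; seeded runs never perturb the caller's RNG
  state (`withr::with_seed`).

## Problem sizes used by the tests and acceptance script

The simulation studies run at desk scale, chosen as the smallest sizes at
which each property is informative: null-calibration uses 100 cohorts
(n = 150, 10% prevalence, 171-point spectra) with 5×5 double CV and
49-permutation tests; selector-recall uses 20 runs of n = 100, p = 200
with 5 planted variables; the end-to-end study uses the full cohort
geometry (n = 599, 26 PE / 21 GH) on a 0.005 ppm grid with 120 alignment
segments. The acceptance script repeats the same computations from
scratch at the sizes recorded in its output.

## Known limitations

* Synthetic spectra are far cleaner than real urine NMR: classification
  metrics on them are substantially higher than anything achievable on a
  real cohort and should be read only as pipeline verification.
* Effect magnitudes and integration windows are package defaults, not
  estimates from data.
* The default (non-nested) selection sequence leaks into cross-validated
  error estimates exactly as the mirrored design does; rely on the
  permutation p-value, or compose the nested variant, when unbiased
  estimates matter.
* Only two-class problems are supported; OPLS-type orthogonal filtering
  and kernel variants are out of scope.
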