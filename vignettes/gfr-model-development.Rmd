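---
title: "Developing and validating GFR estimating models for type 2 diabetes"
author: "gfrdm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing and validating GFR estimating models for type 2 diabetes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gfrdm)
```

## The estimation problem

Glomerular filtration rate is the reference measure of kidney function, but
measuring it directly (isotope clearance) is slow and costly, so clinical
practice relies on estimating equations driven by serum creatinine, age and
sex. In type 2 diabetes those equations degrade: hyperfiltration raises GFR
early in diabetic nephropathy, obesity and reduced muscle mass lower
creatinine for a given filtration rate, and albuminuria tracks the decline
of renal function. `gfrdm` provides the machinery to develop and validate
diabetes-specific estimators — both regression equations and small neural
networks — against a measured reference, and a synthetic-cohort generator
so every stage is exercisable and testable without patient data.

All GFR values are indexed to 1.73 m² body surface area
(mL/min/1.73 m²); no re-normalization is performed anywhere.

## The reference: calibrated imaging GFR

The reference ("standard") GFR is renal dynamic imaging GFR linearly
calibrated to the dual plasma sample ⁹⁹ᵐTc-DTPA clearance. `fit_calibration()`
is plain OLS of dual-plasma on imaging GFR; `dtpa_calibration()` ships the
reference line

$$\text{sGFR} = 3.706 + 1.039 \times \text{imaging GFR} \qquad (R^2 = 0.879,\ n = 36)$$

for use when no calibration pairs are available. OLS (rather than an
errors-in-variables method such as Deming regression) is the convention for
this calibration; the choice matters only if the imaging measurement error
is large relative to the spread of true GFR.

## The two-slope log-spline equations

The creatinine–GFR relationship on the log-log scale is close to piecewise
linear with a bend near the lower end of the normal creatinine range. The
fitted equations therefore model

$$\ln \text{eGFR} = b_0 + b_< \min\!\big(\ln(\text{Scr}/\kappa_{sex}), 0\big)
  + b_> \max\!\big(\ln(\text{Scr}/\kappa_{sex}), 0\big)
  + b_{age}\,\text{Age} + b_F\,[\text{female}] + \textstyle\sum_k b_k x_k$$

with sex-specific knots fixed at $\kappa$ = 0.7 mg/dL (women) and
0.8 mg/dL (men) by default and configurable otherwise. The min/max
parameterization makes the prediction continuous in creatinine at the knot
by construction. BMI, HbA1c and UACR enter on the natural scale, in the
eight combinations of `variable_sets()` (none, each alone, each pair, all
three); age, sex and creatinine are always included. "Log" is the natural
logarithm throughout — the reported summaries are base-ambiguous, and the
natural log matches the CKD-EPI lineage.

`fit_spline_equation()` is ordinary least squares (`stats::lm`) on that
design. There is no variable selection or shrinkage: every covariate of the
chosen set enters and stays. Records missing the outcome or a required
covariate are a hard error — the package never imputes. A rank-deficient
design (e.g., constant creatinine, or a single-sex cohort) raises a
collinearity error naming the aliased columns. Coefficient standard errors
come from the classical OLS covariance and are reported for diagnostics
only.

By default the fit uses the records labelled `development`; the
`pool_internal` flag also pools the internal-validation records. Pooling is
defensible when the internal set is only used afterwards for network
selection, but the default keeps the internal set untouched by any fitting
so that internal-validation MSE remains an honest selection criterion for
both model families.

`smoothing_spline_diagnostic()` (a per-sex `stats::smooth.spline` of
ln sGFR on ln Scr, default 4 equivalent degrees of freedom) is the shape
check that justifies the two-slope form; it is deliberately outside the
prediction path.

## The GABP network

`train_gabp()` composes three stages:

1. **GA initialization** (`ga_optimize_init()`). A chromosome is the
   real-valued concatenation of all weights and thresholds of one network.
   Fitness is the internal-validation MSE reached after a short burst of
   back-propagation from that chromosome (`inner_training_epochs`, default
   50; 0 scores untrained chromosomes — untrained internal MSE turns out to
   be only weakly rank-correlated with trained MSE, so a nonzero burst is
   the default). Evolution is elitist generational replacement: the two
   best chromosomes survive unchanged, the rest are produced by binary
   tournament selection, arithmetic (per-gene blend) crossover with
   probability 0.8, and per-gene Gaussian mutation (rate 0.1, SD 0.1).
   Real coding avoids the precision artifacts of binary coding. The best
   chromosome ever seen is returned, so best-ever fitness is non-increasing
   by construction. Defaults: population 40, 50 generations.

2. **Back-propagation training** (`train_bp()`). Full-batch gradient
   descent with momentum (learning rate 0.05, momentum 0.9, up to 2000
   epochs, early-stop patience 200) on the development-set MSE of the
   scaled output. The returned model is the epoch snapshot with the lowest
   internal-validation MSE. Full-batch makes training invariant to record
   order and deterministic given the starting weights; the analytic
   gradients are verified against central finite differences in the tests.

3. **Hidden-size selection** (`select_hidden_size()`). One network per
   candidate size (1–11 by default), the size with the smallest
   internal-validation MSE wins, ties break toward fewer neurons. With the
   4-input variable set (age, sex, creatinine, BMI) and size 6 this yields
   the 4-6-1 topology.

Architecture choices: hidden neurons use the logistic sigmoid; the output
neuron is linear on a [0,1]-scaled GFR range (linear output is the standard
regression choice and makes degenerate zero-weight networks exactly
analyzable). Inputs are min-max scaled to [0,1] with constants computed on
the development set only and stored in the model, so a serialized model
file is self-contained. Sex is coded female = 1, matching the equations'
female indicator; creatinine enters as its natural log, consistent with the
regression development. A constant input (e.g., a single-sex development
set) is parked at mid-range 0.5 rather than dividing by zero.

**Epoch-budget convention.** When the package compares GA-optimized against
plain random initialization (tests and examples), both arms train the
delivered network with the same back-propagation budget and differ only in
where training starts. The GA's short fitness bursts on candidate
chromosomes are counted as selection overhead, not training — the
comparison isolates initialization quality under an identical training
protocol, which is the claim of interest. A known limitation, and worth
stating plainly: GA initialization does *not* pay for its own epoch cost on
the surfaces tested here — if the epochs spent inside GA fitness evaluation
were instead granted to plain training of a single random start, the plain
arm wins, because full-batch momentum descent on these small smooth
problems keeps improving nearly monotonically with epochs. The GA earns its
keep as a better *starting point*, not as a cheaper optimizer.

## Validation metrics and tests

For paired reference/estimate data (`paired_predictions()`):

* **bias** — median of eGFR − sGFR. The sign convention is configurable
  because the field uses both directions; the default (eGFR − sGFR) makes
  underestimating equations negative.
* **precision** — interquartile range of the differences, type-7
  (linear-interpolation) quantiles. The convention is fixed and documented
  because IQR values depend on it.
* **P30 accuracy** — percent of estimates within 30 % of the reference,
  boundary inclusive (an estimate exactly 30 % off counts as within).

Confidence intervals are percentile bootstrap (2.5th/97.5th percentiles of
the metric over resampled records, 2000 resamples by default),
deterministic for a fixed seed. For the built-in metrics the bootstrap
resamples precomputed per-record errors, which is numerically identical to
resampling rows and much faster.

Model-vs-model comparisons: Wilcoxon signed-rank on per-record absolute
errors (the standard reading of an accuracy comparison; zero pairs dropped,
exact signed-rank null for n ≤ 25 without ties, continuity-corrected normal
approximation with tie correction otherwise) and McNemar on the within-30 %
indicators (exact two-sided binomial for ≤ 25 discordant pairs, chi-square
with continuity correction above). Fully degenerate data (identical models)
return p = 1 with a `degenerate` flag rather than an error. Two-cohort
variable comparisons use Welch's t test for the approximately normal
variables (age, BMI, sGFR) and Mann–Whitney for the skewed labs, with a
small-sample exact path by enumeration of all group assignments (which,
unlike the standard exact algorithm, also handles ties). All tests are
two-sided at α = 0.05; no multiplicity correction is applied.

`table3_report()` assembles all of this into one row per model against a
designated reference; the reference compared with itself is degenerate and
reports p = 1.

## What the synthetic cohorts do and do not emulate

`cohort_sim_config()` defaults reproduce the development cohort's
marginals: sex Bernoulli(0.543 male); age truncated normal
59.8 ± 13.1 y (≥ 18); BMI truncated normal 25.0 ± 3.5 kg/m²; Scr, HbA1c and
UACR log-normal parameterized from their reported median/IQR by matching
the 25th/75th percentiles (`lnorm_from_median_iqr()`); the log-normal
choice reflects the strong right skew of these labs (the UACR IQR is five
times its median). Reported summaries do not identify the distribution
families, so these are modelling choices, made once.

Standard GFR is generated as `truth(record) × exp(ε)` with
ε ~ N(0, `noise_sigma`²). The default truth model
(`default_truth_model()`: intercept 4.90, slopes −0.35/−1.10 below/above
the knot, −0.007 per year, +0.02 female) is a CKD-EPI-lineage shape chosen
so simulated sGFR lands near 80 ± 30 mL/min/1.73 m² at the default
covariate marginals; the default noise (`noise_sigma = 0.25` on the log
scale, ≈ 25 % CV) represents the combined biological and measurement
variability around a structural model.

Covariates are independent by default; an optional Gaussian-copula
correlation matrix induces joint structure without changing the marginals.
What the generator does **not** emulate: the clinical exclusion cascade
(edema, dialysis, acute creatinine change, ...), diabetes duration, any
covariate–covariate structure beyond the optional copula, and any
truth-model misspecification — so a passing recovery test shows the
estimators work when their form is right, not that the form is right for
real patients.

Cohort summaries (`summarize_cohort()`) use left-closed, right-open
clinical bins (a BMI of exactly 25 falls in 25–30; an sGFR of exactly 90
falls in > 90 — the boundary convention is not standardized and is simply
fixed here), and the SD of a singleton sample is reported as 0.

## Numerical and design choices

* Creatinine is stored internally in mg/dL only; µmol/L input is converted
  by the standard factor 88.4.
* The CKD-EPI below-knot exponent is implemented with its standard negative
  sign (α = −0.329 female / −0.411 male). Some transcriptions print α
  positive, which would make eGFR rise with creatinine below the knot;
  `as_printed = TRUE` reproduces that variant for auditing, and a property
  test pins the default to monotone non-increasing behaviour.
* The 2:1 development/internal split is simple unstratified randomization
  (nothing suggests stratification was used); development receives
  `round(n × f)` records, clamped so both sets are non-empty, and external
  records are never reassigned.
* All stochastic operations take explicit seeds and restore the caller's
  RNG state; the pipeline refuses to run without a seed. Model files and
  cohort files are written with 17 significant digits so write/read round
  trips are exact.
* Degenerate inputs fail loudly with classed conditions
  (`gfrdm_validation_error`, `gfrdm_collinearity_error`, ...) rather than
  returning silently wrong numbers; the CLI maps validation/configuration
  errors to exit code 2 and computation errors to 3.

## Problem sizes

The shipped examples, tests and the acceptance script run at deliberately
modest scale, chosen to exercise every code path at high statistical
resolution while remaining quick on a single CPU: pipelines at the study's
414 + 105 scale with hidden-size search over {4, 6, 8}, 300 BP epochs and a
GA of population 12 over 6 generations; coefficient-recovery checks at
n = 5000; bootstrap coverage at 600 replications of 2000 resamples. The
function-level defaults (hidden sizes 1–11, 2000 epochs, GA 40 × 50) are
the full-scale settings a real development study would use.

## Limitations

* The GABP hidden-size search and GA are composed sequentially (GA per
  size, then selection); a nested or interleaved design is equally
  plausible and is not implemented.
* Percentile bootstrap CIs slightly under-cover for strongly discrete
  statistics at small n; the coverage test pins behaviour only for the
  median at n = 500.
* The network family is deliberately small (one hidden layer, ≤ 11
  neurons, full-batch descent); no regularization, minibatching or
  alternative optimizers.
* Synthetic validation cannot establish clinical performance; it
  establishes that the machinery recovers known truths under its own
  assumptions.
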