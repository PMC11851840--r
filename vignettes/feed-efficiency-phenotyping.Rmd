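---
title: "Feed-efficiency phenotyping from automatic feeder data: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feed-efficiency phenotyping from automatic feeder data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Feed conversion ratio (FCR, kg feed per kg gain) drives most of the cost of
producing a market pig, but measuring it individually requires months of
automatic feeding station (AFS) records, and those records are noisy: missing
ear-tag reads, negative intakes, impossible feed rates. Two animals also
rarely cover the same weight range during a test, so their raw cumulative
feed intakes (CFI) are not comparable. `pigfcr` implements a pipeline that
turns visit-level AFS records into a standardized 30--120 kg CFI (and hence
FCR) phenotype, asks how short a measurement window can be without losing
ranking accuracy, and predicts the full-range CFI from an 80--110 kg window.

The package is exercised end-to-end on a synthetic herd generator because
per-visit AFS records of this kind are proprietary; every stage is therefore
testable against known ground truth.

## The synthetic herd generator

Each animal grows along a three-parameter logistic,
$BW(a) = BW_{max} / (1 + e^{(x_{mid}-a)/scal})$ with age $a$. The generator
draws, per animal: entry weight $\sim N(28.30, 1.02^2)$ kg, 30--120 kg
average daily gain (ADG) $\sim N(1.02, 0.12^2)$ kg/d, asymptote
$BW_{max} \sim N(170, 10^2)$ kg, and FCR $\sim N(2.31, 0.27^2)$ kg/kg (all
truncated to physiological ranges). Rather than drawing the curve steepness
independently, $scal$ is derived from the drawn ADG and $BW_{max}$ through
the 30-to-120 kg transit time $90/\mathrm{ADG}$, and $x_{mid}$ from the
entry weight; this pins the realized ADG and FCR distributions to the
configured herd moments exactly, which independent draws of $scal$ would
only approximate. Entry age is 70 d; the default test length of 130 d lets
nearly every animal cross 120 kg.

Daily feed is gain times the animal's FCR plus $N(0, 0.35^2)$ kg/d noise
(entry day intake is zero, so the noise-free CFI at weight $w$ is exactly
$\mathrm{FCR}\cdot(w - BW_{entry})$). Daily observed weight adds
$N(0, 1^2)$ kg weighing noise; visits within a day add 0.2 kg jitter. The
day's feed is split over $\max(\mathrm{Pois}(7.93),\lceil g/700\rceil)$
visits as an equal base share plus bounded uniform jitter — the split sums
exactly and keeps every share under 1400 g, which combined with per-animal
feed rates truncated to 25--340 g/min (drawn from $N(45.65, 23.94^2)$)
guarantees that clean visits satisfy all eight QC rules by construction.
The truncation slightly inflates mean occupation time relative to a real
herd; occupation-time summaries are not phenotypes here, so we accept that.

Anomalies of the eight QC error classes are injected at a configurable
per-visit rate (default 0.15% per class, about 1.2% overall, matching the
order of exclusions a commercial QC pass produces). Each injected value is
drawn uniformly inside the violating region of its rule, placed so that the
targeted rule is the lowest-index rule violated; the clean value is kept in
the ground truth so imputation accuracy is measurable.

What the generator does *not* emulate: diurnal feeding rhythms, social
competition at the feeder, pen effects, diet-phase changes, and — most
importantly — curvature in the CFI-vs-BW relationship. Because each
animal's FCR is constant over the test, synthetic CFI is linear in BW up to
noise. Consequences: the CF coefficient centers on 1.0 (a real herd, whose
feed-per-kg rises with weight, gives CF near 1.03 and a more negative A),
the quality gates retain nearly every animal, and correction/prediction
correlations on synthetic herds (~0.99/0.94) sit above what heterogeneous
real data would give. Passing tests demonstrate the machinery is correct
and calibrated, not that a commercial herd would reach the same numbers.

## Quality control

Eight visit-level rules on intake per visit (FIV, g), occupation time per
visit (OTV, s) and feed rate per visit (FRV = FIV/(OTV/60), g/min):
negative FIV; FIV > 2000 g; |FIV| > 20 g at OTV = 0; negative OTV;
OTV > 3600 s; FRV > 500 g/min when 0 < FIV < 50 g; FRV > 350 g/min when
FIV > 50 g; FRV = 0 at OTV > 500 s. All are strict inequalities on single
visits; a visit is removed iff it violates at least one rule, with
reporting attributed to the lowest-index violated rule (the removal set is
order-independent). FRV at OTV = 0 with nonzero intake is treated as
$\pm\infty$ so the rate rules also catch zero-time intakes. Records with
missing fields are dropped before rule evaluation and counted separately.
Removal is per visit, not per day — the rules are visit-level predicates
and a bad visit says nothing about its neighbours.

## Growth models

**Robust regression.** Per animal, BW ~ day is fit by Huber M-estimation
(tuning constant 1.345, IRLS, up to 100 iterations, MAD scale) — `rlm` in
the `MASS` sense. The slope is the animal's ADG; animals with
pseudo-R² < 0.8 are excluded. Pseudo-R² is defined here as the squared
Pearson correlation between fitted and observed BW: it is bounded in
[0, 1] and reduces to ordinary R² under OLS. On an exact line the
M-estimate's scale collapses, so perfect fits short-circuit to OLS.

A caveat surfaced by testing: on a *curved* noise-free trajectory the
Huber slope differs from the least-squares slope by a few thousandths of
kg/d, because curvature residuals are downweighted asymmetrically. ADG
recovery checks therefore use linear-truth trajectories, where "the true
ADG" is unambiguous; on logistic trajectories any slope-functional choice
of truth silently favours one estimator.

**Logistic population fit.** Nonlinear least squares
(Levenberg--Marquardt via `minpack.lm`, ftol 1e-10) with data-driven
starts: $BW_{max}^0 = 1.05\max(BW)$, $x_{mid}^0$ = the day nearest half of
that, $scal^0$ = day range / 8. Non-convergence (including flat data) is
flagged honestly and the best iterate returned.

**Weight--day inversion.** Crossing days for a target weight come from the
robust-fit *line*, not raw noisy weights: fractional
$day = (w - b)/a$, restricted to the observed span. Animals rarely weigh
exactly 30 or 120 kg on an observation day, so all weight boundaries are
fractional-day interpolations; targets outside the fitted span raise an
error naming the animal rather than extrapolating.

## Visit-intake correction

Intakes more than three standard deviations from the population mean
(strict inequality, population not per-animal statistics) are flagged in a
single pass. The intake model FI ~ BW + T + BW:T is fit on unflagged
visits only — fitting before flagging would hand the outliers leverage
over their own correction. The printed model form carries no intercept or
error term; we include an overall intercept, and the reporting of marginal
vs conditional R² implies a grouping structure, implemented as a
per-animal random intercept fit by REML (`lme4`), the only random
structure a single grouping factor supports. Marginal and conditional R²
follow the Nakagawa decomposition (fixed variance over fixed + random +
residual). T is per-visit occupation time, since imputation targets single
visits. Degenerate fits (e.g. noise-free data) fall back to the
fixed-effects model with zero random variance. Flagged intakes are
replaced by the model prediction — fixed effects plus the animal's random
intercept when known — with negative predictions clipped to zero under a
warning.

## CFI standardization (CF and A models)

Per animal, CFI is regressed on BW over the records in the 25--50 kg and
100--140 kg flanks; animals with R² < 0.9 are excluded. CFI is the
*response* (CFI = A + b·BW): that orientation gives the intercept A units
of kg feed, which is what the A-model formula divides by body weight. The
endpoint chord slope uses $CFI_{end}/(BW_{end}-BW_{in})$ — CFI is zero at
entry by definition — and CF is best-fit slope over chord slope.

$$CFI_{120CF} = CFI_{end} - (BW_{end}-120)\,\frac{CFI_{end}}{BW_{end}-BW_{in}}\,CF
\qquad CFI_{30CF} = (30-BW_{in})\,\frac{CFI_{end}}{BW_{end}-BW_{in}}\,CF$$

$$CFI_{120A} = CFI_{end} + (120-BW_{end})\,\frac{CFI_{end}-A}{BW_{end}}
\qquad CFI_{30A} = (30-BW_{in})\,\frac{CFI_{end}-A}{BW_{end}}$$

Both reduce to $CFI_{end}$ when the animal finishes at exactly 120 kg. The
regression reference $CFI_{reg}$ is the fitted line anchored at the entry
weight (line value minus line value at $BW_{in}$), so
$CFI_{reg,120}-CFI_{reg,30} = 90b$ identically, and on exactly linear data
CF-model (CF = 1), A-model (A = intercept) and reference agree to
floating-point precision — a key correctness invariant.

Population-mean CF and A are applied uniformly to every animal, the way a
breeding program publishes a single correction factor (the same logic as
age-at-100-kg corrections); per-animal coefficients are retained for
diagnostics.

## Window analysis and breakpoint

For every window on the 10-kg grid inside 30--120 kg (sizes 10--80 kg),
the window FCR is (CFI at window end − CFI at window start)/size, with CFI
at a weight interpolated as above. The informativeness of a window is the
Spearman correlation (average ranks on ties) across animals between window
FCR and overall FCR, where overall FCR is $CFI_{reg,30-120}/90$ — the
regression value is the designated unbiased estimate, so it is the
correlation target throughout. Animals not spanning a window are dropped
from that window rather than extrapolated (extrapolation would leak the
linear-fit assumption into the correlation); per-size summaries are
unweighted means over the size's windows.

The size--correlation curve is then fit with a continuous two-segment
linear model. The breakpoint is found by exhaustive search on a 0.1-kg
grid over the open interior, each candidate scored by the RSS of the
constrained two-segment OLS fit, ties broken toward the smaller
breakpoint. At eight data points an exhaustive grid is cheap,
deterministic, and verifiable against a brute-force oracle, which an
iterative-linearization breakpoint search is not; collinear inputs are
reported with a no-elbow flag rather than a spurious breakpoint. The
selected module size is the breakpoint rounded to the 10-kg grid.

## Bayesian ridge prediction

The 30--120 kg CFI is predicted from a short window as
$CFI_p = \beta_1 BW_{in} + \beta_2 BW_{out} + \beta_3 CFI_{window} +
Intercept$. "Bayesian ridge regression" is implemented in its standard
evidence-maximization (type-II maximum likelihood) sense: Gaussian noise
precision $\alpha$ and isotropic Gaussian prior precision $\lambda$ on the
coefficients, both estimated by the MacKay fixed-point iteration with flat
hyperpriors, converging at relative change < 1e-8 (max 300 iterations).
Predictors are centered and scaled internally — ridge penalties are
scale-sensitive — and coefficients are reported back on the original
scale; the intercept is unpenalized. Constant columns (e.g. the window
bounds, identical for every animal when windows are weight-defined) are
dropped with a zero coefficient and a warning rather than an error, since
the remaining window-CFI predictor carries the signal. Either
hyperparameter can be frozen, in which case the solver reproduces the
closed-form ridge solution — the oracle the tests check against at 1e-9.

The regression target is $CFI_{reg,30-120}$, not the raw summed CFI: the
reference value is the designated unbiased estimate and predictions are
validated against it. Cross-validation shuffles *animals* (fold assignment
depends only on the animal set and seed, not row order) into k disjoint
folds; both k = 5 and k = 10 are reported, with per-fold MSE/RMSE/R² and
pooled out-of-fold Spearman and Pearson correlations. FCR is derived from
predicted CFI as CFI/90 kg by default (FCR's kg/kg units); a per-day
variant (CFI divided by measurement days) exists behind a flag — the two
conventions disagree in the source literature and we assert neither.
Note that with the shared 90-kg denominator, FCR correlations equal CFI
correlations exactly.

## Pipeline and validation

`run_pipeline()` chains the stages on a training herd, then applies the
learned correction coefficients and ridge model, frozen, to a validation
herd simulated with a different seed and slightly shifted generator means
(entry +0.4 kg, ADG −0.02 kg/d, FCR +0.03 — a batch effect). All
randomness flows from the named seeds in the config; tests assert that
perturbing the validation seed leaves every training artifact bit
identical, and that record counts chain stage to stage.

## Problem sizes and numerical choices

The analysis drivers and the acceptance script use the study-scale herds
(987 training + 150 validation animals, ~1M visits); the unit-test suite
uses herds of 5--200 animals, which exercise every code path in seconds.
Tolerances: exact identities at 1e-9; IRLS at 1e-8 relative; NLS at
1e-10; evidence fixed point at 1e-8. Degenerate inputs (flat trajectories,
constant predictors, zero-variance targets, empty gates) return flagged
results or informative errors rather than NaN.

## Known limitations

* Synthetic linearity of CFI vs BW (see above): CF ≈ 1.0 and A ≈ −64 kg
  on synthetic herds, versus ~1.03 and ~−104 kg on real curved data; the
  formulas are exercised over their full parameter ranges in tests, but
  herd-level coefficient values here characterize the generator, not any
  real population.
* The intake model's marginal R² (~0.72 on synthetic herds) is driven by
  the generator's feed-rate heterogeneity; real visit data have richer
  covariance between weight, time and intake.
* Windows are weight-indexed; day-indexed windows are out of scope.
* No pen, station, diet-phase or breed effects anywhere in the generator
  or models.
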