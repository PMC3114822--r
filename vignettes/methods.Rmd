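---
title: "Models and methods in mobilegam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in mobilegam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobilegam)
```

`mobilegam` estimates near-road air pollution gradients from 1-minute
mobile-monitoring data collected by walkers carrying particle counters
through a neighbourhood flanked by two major line sources — an at-grade
expressway and a bridge whose deck rises to roughly 40 m. This vignette
documents the statistical models, the numerical choices behind them, the
synthetic campaign generator used for validation, and the limitations of
both.

## The additive model

For minute $i$, the log concentration is modelled as

$$Y_i = X_i\beta + f_{WB}(d_{WB,i}) + f_{BQE}(d_{BQE,i}) + f_s(s_i) +
\varepsilon_i,$$

with $X_i$ the linear covariates — per-roadway traffic (veh/min), wind
speed (m/s), temperature (°C), relative humidity (%), and sampling-day
dummies — $f_{WB}, f_{BQE}$ smooth functions of the distance to each road,
and $f_s$ a bivariate smooth of UTM location that absorbs residual spatial
structure (local sources other than the two roads). Natural logarithms are
used throughout: the percent-decrease summary
$100\,(1 - e^{\eta(100) - \eta(d_{\min})})$ is exact on that scale.

Distances are Euclidean point-to-polyline distances in planar UTM metres.
For the elevated bridge an *effective distance* $\sqrt{h^2 + g^2}$ is used,
where $g$ is the horizontal nearest distance and $h$ the deck height at the
nearest point, linearly interpolated along the elevation profile. The
package does no geodesic computation; inputs must already be projected.

### Spline bases and penalties

All smooths are built with `mgcv`'s constructors and fitted as penalized
regression splines with REML-selected smoothing parameters (`gam` with
`paraPen` on explicitly assembled design matrices, so that the same solver
serves the whitened generalized-least-squares problems below). GCV is
available behind a flag; REML is the default for its better-behaved
optimum. Each smooth carries a sum-to-zero constraint over the observed
covariate values, absorbed into the basis.

* **Distance smooths** (`k = 10`): cubic regression splines built on the
  *square-root* of distance, evaluated and reported in metres. Near-source
  decay concentrates its curvature in the first tens of metres; on the raw
  scale, quantile knots and a global roughness penalty systematically
  flatten the steep near-road rise (in decay-plus-noise simulations the
  recovered 100-m decrement was biased several percentage points low),
  while on the root scale curvature is spread evenly and recovery is
  near-unbiased. This is a smoothness-prior choice, not a change of model
  class.
* **Spatial smooth** (`k = 30`): low-rank thin-plate regression spline of
  the coordinate pair with the standard thin-plate penalty and an
  unpenalized affine null space.
* **Per-shift time smooths** (`k = 10` per shift): one centred cubic
  spline of minutes-into-shift per sampling shift, assembled as a single
  block-diagonal term with one *shared* smoothing parameter (factor-smooth
  style). A shared parameter keeps the fit fast and stable with 12 shifts;
  shifts too short for a smooth degrade to a centred linear trend.
* Distance covariates with fewer than 25 distinct values fall back to
  `k = min(k, n_distinct - 2)`.

Basis dimensions are defaults, not estimates; they were chosen generously
relative to the effective degrees of freedom the data support and are
config-overridable.

## AR errors and whitening

Minute-scale serial correlation is strong along a walking route. The AR
model keeps the additive mean structure but takes $\varepsilon_i$ to follow
an AR($p$) process *within one backpack's shift* (three simultaneous
backpacks interleave within a shift, so shift-level grouping would misread
the lag structure; correlation never crosses shift or backpack boundaries).

The order and coefficients are determined empirically from the initial
additive model's residuals: autocovariances are computed within each
backpack-shift series, pooled with length weights, and Levinson–Durbin
gives the Yule–Walker fit for each order $0..5$; the order minimising BIC
on the pooled innovation variance is kept. BIC rather than AIC because
order *identification* needs a consistent criterion — AIC's non-vanishing
overfitting probability selects spuriously high orders in a substantial
fraction of campaigns, which we verified in simulation (AIC picked the true
order in only ~60–75% of synthetic campaigns; BIC in essentially all).

With the AR parameters fixed, the refit is exact penalized generalized
least squares: response and all design columns are transformed by the AR
innovations filter (the first $p$ rows of each series use the
Levinson–Durbin partial predictors, scaled to unit innovation variance, so
the implied transform $W$ satisfies $WVW' = I$), and the identical
penalized solve is applied. Smoothing parameters are re-selected on the
whitened problem, matching the two-stage fixed-AR logic. Gaps from QC
exclusions within a series are treated as contiguous minutes — an
approximation that slightly understates correlation across gaps.

Coefficient intervals use the Bayesian/conditional covariance of the
penalized fit (the standard choice for smooth CIs, conditional on the
selected smoothing parameters; smoothing-parameter uncertainty is not
propagated — a known, documented limitation). Smooth-term p-values are
approximate Wald statistics on the term's coefficient block referred to a
chi-square with the term's effective degrees of freedom.

## The time-trend model

Replacing day dummies by shift main effects (shift nests day) and adding
the per-shift time smooths yields the long-term time-trend model, with AR
errors handled by the same two-stage procedure. Its purpose is diagnostic:
when the shared background trend and the time-varying covariates carry the
same slow structure, concurvity lets the time smooths absorb covariate
signal and the meteorological estimates move toward the null. The package's
concurvity scenario makes this mechanism explicit: the generator couples the
shared background to low-wind stagnation (`trend_wind_gain`), so the AR
model — blind to the trend — overstates the wind effect, and the time-trend
model removes the shared part.

## The discretized line-source model

Both roads are cut into 10-m segments (the final partial segment is kept,
its weight scaled by its length fraction). Each segment $j$ acts as an
individual source with per-minute weight $e_j$ (its static weight times the
road's disaggregated traffic count), and a single pooled kernel $g$ is
estimated through design columns $\sum_j e_j B_k(d_{ij})$, with $d_{ij}$
the segment distance (height-corrected via the same $\sqrt{h^2+g^2}$ form,
using the segment midpoint). Both roads share one $g$; a per-road variant
exists but is off by default.

Two identifiability choices: the constant direction of the basis (cardinal
cubic splines sum to one) is removed by an orthonormal reparameterization,
since it is collinear with the intercept and traffic columns; and because
scaling all $e_j$ by $c$ rescales $g$ by $1/c$, curves are reported
recentred so only shape is interpreted. `aggregate_source_curve()` converts
the kernel into the implied total road curve
$F(p) = \sum_j e_j\,g(d_{pj})$ at probe points, the object comparable to a
direct distance smooth. In simulation the recentred kernel's *shape*
reproduces the direct distance curve within its pointwise band, while the
implied aggregate curve is attenuated by roughly a quarter in the first
tens of metres — deconvolving a sharp near-road peak from line-integrated
contributions is intrinsically harder than smoothing distance directly, so
the discretized model is best read qualitatively, as a robustness check on
the curve shape.

## The synthetic campaign generator

The generator emulates the campaign the models were designed for, and its
defaults are the study conditions:

* **Design**: 12 shifts (09:00 and 14:00, two per day over six days) of
  165 min, three backpacks walking waypoint routes at 60 m/min in an
  800 m × 800 m UTM box; half the waypoints are drawn in 150-m corridors
  along the roads, emulating scripted routes that cover every street with
  emphasis near the sources (and guaranteeing every 50-m distance band out
  to 500 m holds at least 1% of minutes, so the distance smooths are
  estimable).
* **Sources**: an at-grade north–south expressway (three counters) and an
  east–west bridge ramping 0 → 40 m (two counters). Per-minute road
  totals centre on 13.7 (bridge) and 36.7 (expressway) veh/min, drawn as
  truncated-normal 15-min interval counts split evenly across counters,
  with binomial vehicle-class and multinomial speed splits.
* **Meteorology**: log wind speed = a slow within-shift sinusoid
  (amplitude 0.7) plus minute-scale AR(1) noise, total log-sd 0.843 and
  median 0.9 m/s — reproducing a low-wind regime with ~55% of minutes
  below 1 m/s and a realistic slow component (without which the concurvity
  scenario above could not exist). Wind direction wanders around a
  per-shift base. Temperature (mean 26.3 °C, warmer afternoons, slow
  drift) and RH (mean 45.8%, anti-correlated with temperature) share one
  virtual fixed station.
* **Truth**: log concentration is assembled as intercept + day offset +
  within-shift trend + $X\beta$ + road decays + a spatial field of 2–4
  Gaussian bumps (≤ 0.15 log-units, away from the roads) + AR noise, and
  the per-row components are serialized so tests can verify the
  reconstruction identity exactly. The `ufp_default` preset uses an
  exponential decay (range 60 m, levelling off beyond ~150 m) whose true
  0-to-100-m decrement is 17.5% — the centre of the plausible near-road
  band for an ultrafine channel — with AR(1) noise ($\phi = 0.5$,
  innovation sd 0.30); `pm25_default` uses a small linear decay (3% per
  100 m), a dominant day/shift background, strong meteorology effects and
  AR(3) noise (partial autocorrelations 0.45/0.25/0.20, innovation sd
  0.20); `null_decay` removes the distance effect; `sector_decay` applies
  the expressway decay only downwind. Covariate coefficients are set to
  published AR-model point estimates for comparable campaigns, so recovery
  checks work on field-realistic magnitudes.

What the generator does *not* emulate: street-network routing (walkers move
freely), instrument drift and inter-operator calibration error, congestion-
dependent emission factors, building wakes or street-canyon dispersion, and
real counter subsets (per-road totals are split evenly). Passing recovery
tests therefore demonstrates that the estimators are correct and calibrated
under the stated error model at realistic sizes and noise levels — not that
field data meet those assumptions.

## Numerical and degenerate-case choices

* Nearest-point ties on a polyline go to the lowest segment index.
* The wind-sector rule is made fully explicit: *downwind* iff the
  blowing-toward bearing is within 90° of the road→point bearing **and**
  more than 45° off the local road axis (either sense); boundary angles
  classify upwind; calm minutes (speed ≤ 0 by default) get a `calm`
  sentinel excluded from stratified fits. The local segment orientation at
  the nearest point is used, since the rule must work for bent roads.
* Traffic medians split with ties to the low stratum.
* QC floors default to 1,000 particles/cm³ (UFP) and 1 µg/m³ (PM2.5);
  exclusions above 5% trigger a warning.
* Zero-variance responses (and rare optimizer failures) fall back to a
  direct penalized solve at unit smoothing parameters, exact in the
  degenerate case.
* Stratified sensitivity refits skip strata under 200 rows.
* Surface maps use `k = 60` (richer than the model's adjustment surface),
  a 10-m lattice, and mask cells more than 100 m from any observation.
* Every stochastic routine is seeded; the campaign default is 20110124.

## Problem sizes used in the test suite

Paper-scale validation campaigns use 12 shifts × 3 backpacks × 70 min
(~2,500 rows, matching the size at which the models are meant to operate);
calibration sweeps use 20–50 campaigns; interval-calibration replicates use
a reduced 6-shift × 84-min single-backpack design (~500 rows, 200
replicates). These sizes give stable medians and binomial margins while
keeping a full validation run in the minutes range.

## Known limitations

* Intervals are conditional on the selected smoothing parameters and AR
  coefficients; neither source of selection uncertainty is propagated.
  Empirically the wind-coefficient interval coverage sits near the low
  edge of nominal (~90–93%) under the default scenario, which also
  includes a mild unmodelled within-shift trend.
* The smooth-term test is an approximation; treat p-values near a decision
  boundary with care.
* The distance-curve reference point is the minimum *observed* distance,
  which is a random quantity; for an elevated road it cannot be smaller
  than the local deck height.
* Models including the spatial smooth and time smooths are not suitable
  for out-of-sample exposure prediction; the statistical covariates are
  campaign-specific.
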