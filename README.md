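# mobilegam

Additive models with autoregressive errors for quantifying near-road air
pollution gradients from mobile monitoring.

## The problem

Walking a study area with backpack monitors yields thousands of 1-minute
pollutant readings (ultrafine particle counts, PM2.5) scattered over space
and time. Those data confound three things: genuine spatial gradients away
from line sources (highways, elevated bridges), temporally varying
meteorology and traffic, and strong minute-scale serial correlation along
each walking route. `mobilegam` implements a regression framework that
separates them and quantifies the concentration decline with distance from
each roadway, for exposure scientists and environmental epidemiologists
working with mobile-monitoring campaigns.

## The models

The core model for the log concentration Y_i of minute i is the additive
structure

    Y_i = X_i beta + f_WB(d_WB,i) + f_BQE(d_BQE,i) + f_s(s_i) + eps_i

where X_i holds per-roadway traffic counts (15-min counter totals spread
uniformly, 1/15th per minute), wind speed, temperature, RH and sampling-day
dummies (all linear); f_WB and f_BQE are penalized cubic spline smooths of
the distance to each line source (an *effective* distance
sqrt(height² + horizontal²) for the elevated bridge); and f_s is a low-rank
thin-plate smooth of UTM location absorbing residual spatial structure.
Smoothing parameters are chosen by REML.

Three refinements mirror field practice:

* **AR model** — the errors eps_i within one backpack's shift are given an
  AR(p) structure whose order is selected empirically from the additive
  model's residuals (pooled within-shift Yule–Walker, BIC over p = 0..5);
  the model is then refit by penalized generalized least squares, whitening
  the response and design with the fixed AR innovations filter.
* **Time-trend model** — adds a main effect of sampling shift and one
  centred smooth of time within each shift, again with AR errors; it
  illustrates how concurvity with shared temporal trends pulls
  meteorological coefficients toward the null.
* **Discretized line-source model** — cuts both roads into 10-m segments,
  treats every segment as an individual source with traffic weight e_j, and
  estimates one pooled distance kernel g through design columns
  sum_j e_j B_k(d_ij).

The quantity of interest is the adjusted distance-decay curve with
pointwise 95% CI and its summary `pct_decrease_100m` =
100·(1 − exp(eta(100) − eta(d_min))), the percent concentration decrease
between the road-edge reference and 100 m.

Because no field campaign ships with the package, a synthetic campaign
generator (`preset()`, `generate_campaign()`) produces complete
observation/traffic/weather/road datasets with a documented ground truth
(`truth.json`): scripted-walk routes, a 0→40 m elevated bridge, low-wind
meteorology, and AR(1) or AR(3) minute noise. Every estimator is validated
by recovering those truths.

## Worked example

```r
library(mobilegam)

cmp <- generate_campaign(preset("ufp_default", seed = 1))
fr  <- campaign_frame(cmp)      # QC + traffic disaggregation + stream join
fit <- fit_ar(fr)               # additive fit, AR selection, GLS refit
fit
#> ar model for ufp: n = 5940, R2 = 0.146
#>   AR(1) errors, phi = 0.519
#>   WB: 17.4% decrease within 100 m
#>   BQE: 18.7% decrease within 100 m
cmp$truth$true_pct_decrease_100m
#> $wb
#> [1] 17.50221
#> $bqe
#> [1] 17.50221
```

The fitted AR order (1, coefficient 0.52 against an injected 0.5) and the
100-m decrements recover the generator's documented truth (17.5% on both
roads). `fit$table` holds the
estimate / 95% CI / p table for every covariate, `fit$curves$BQE` the
distance curve with its confidence band, and
`results_tables(list(additive = ..., ar = ..., timetrend = ...))` writes
the side-by-side model-comparison table.

The numbered scripts under `analysis/` run the full study end to end
(simulation, the three models per pollutant, distance curves, sensitivity
refits, surface maps) and write their tables under `results/`.

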