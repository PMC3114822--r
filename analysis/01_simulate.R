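#!/usr/bin/env Rscript

## Step 1 — generate the synthetic mobile-monitoring campaigns.
##
## Two campaigns are written under results/campaigns/: an ultrafine-particle
## scenario (nonlinear near-road decay, AR(1) minute noise) and a fine-
## particle scenario (small linear decay, dominant temporal background,
## AR(3) noise). Each directory holds the observation, traffic and weather
## streams, the road geometries, and truth.json with the generator's ground
## truth.

library(mobilegam)

dir.create("results/campaigns", showWarnings = FALSE, recursive = TRUE)

for (name in c("ufp_default", "pm25_default")) {
  cmp <- generate_campaign(preset(name, seed = 20110124))
  out <- file.path("results/campaigns", name)
  write_campaign(cmp, out)
  cat(sprintf("%s: %d observation rows, %d shifts x %d backpacks -> %s\n",
              name, nrow(cmp$observations), cmp$config$n_shifts,
              cmp$config$n_backpacks, out))
  cat(sprintf("  true 100-m decrement: WB %.1f%%, BQE %.1f%%\n",
              cmp$truth$true_pct_decrease_100m$wb,
              cmp$truth$true_pct_decrease_100m$bqe))
}
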