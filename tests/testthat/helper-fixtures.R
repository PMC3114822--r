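## Shared fixtures, all generated in code.

## a small but fittable campaign (one backpack keeps unit tests fast)
small_campaign <- function(seed = 11, preset_name = "ufp_default", ...) {
  generate_campaign(preset(preset_name, n_shifts = 4, minutes_per_shift = 60,
                           n_backpacks = 1, seed = seed, ...))
}

small_frame <- function(seed = 11, ...) {
  campaign_frame(small_campaign(seed, ...))
}

## straight E-W test road at y = 0
straight_road <- function(len = 100, elev = 0, id = "R") {
  road_source(id, rbind(c(0, 0), c(len, 0)), elevation = elev)
}

## results of the heavier paper-scale sweeps, computed once per test run
.accept_env <- new.env(parent = emptyenv())

## 20-seed paper-scale UFP sweep: additive + AR fits per seed
ufp_sweep <- function(n_seeds = 20) {
  key <- paste0("ufp", n_seeds)
  if (!is.null(.accept_env[[key]])) return(.accept_env[[key]])
  out <- lapply(seq_len(n_seeds), function(i) {
    cmp <- generate_campaign(preset("ufp_default", minutes_per_shift = 70,
                                    seed = 20110124 + i))
    fr <- campaign_frame(cmp)
    fa <- fit_additive(fr)
    far <- fit_ar(fr)
    list(truth = cmp$truth,
         order = far$ar$order,
         pct_ar = c(WB = attr(far$curves$WB, "pct_decrease_100m"),
                    BQE = attr(far$curves$BQE, "pct_decrease_100m")),
         ciw_ar = c(WB = attr(far$curves$WB, "ci_width_100m"),
                    BQE = attr(far$curves$BQE, "ci_width_100m")),
         ciw_add = c(WB = attr(fa$curves$WB, "ci_width_100m"),
                     BQE = attr(fa$curves$BQE, "ci_width_100m")))
  })
  .accept_env[[key]] <- out
  out
}
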