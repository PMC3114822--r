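## Synthetic mobile-monitoring campaign generator with documented ground
## truth. Emulates a three-week urban campaign around two line sources (one
## elevated), scripted-walk routes, 15-min traffic counters, a single fixed
## weather station with predominantly low wind speeds, and minute-scale
## AR noise within each backpack's shift series.

#' Scenario configuration for the campaign generator
#'
#' All knobs of [generate_campaign()], with defaults matching the emulated
#' campaign: 12 shifts (2 per day, 09:00 and 14:00) of 165 min, three
#' backpacks, an at-grade expressway-like road and a bridge-like road ramping
#' 0 to 40 m elevation, per-minute road traffic around 13.7 (bridge) and
#' 36.7 (expressway) vehicles, and log-normal wind speeds with median 0.9
#' and 95th percentile 3.6 m/s.
#'
#' @param seed Integer RNG seed (default 20110124).
#' @param n_shifts,minutes_per_shift,n_backpacks Campaign size.
#' @param domain Bounding box `c(xmin, xmax, ymin, ymax)` in metres (UTM).
#' @param walk_speed Metres walked per minute (default 60).
#' @param truth List of ground-truth components (see Details).
#' @param met List of meteorology parameters.
#' @param traffic List of traffic parameters.
#' @param start_iso Campaign start day (first sampling day, UTC).
#' @details The `truth` list holds: `intercept`; named `beta` for
#'   `traffic_wb`, `traffic_bqe`, `wind_speed`, `temperature`, `rh`;
#'   `day_offsets` (recycled over days, first day is reference 0);
#'   `decay_wb`/`decay_bqe` (`list(form = "exp", amplitude, range)` for
#'   `A*exp(-d/range)` or `list(form = "linear", slope, max_d)` for
#'   `-slope*min(d, max_d)`); `sector_only` (`NULL`, or `"bqe"`/`"wb"` to
#'   apply that road's decay only to downwind minutes); `spatial` (data
#'   frame `x`, `y`, `amp`, `sd` of Gaussian bumps); `trend_amplitude` and
#'   per-shift phases for the shared sinusoidal within-shift trend; `ar`
#'   (`list(order, phi, sd)` innovation structure per backpack-shift).
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(seed = 20110124,
                            n_shifts = 12, minutes_per_shift = 165,
                            n_backpacks = 3,
                            domain = c(0, 800, 0, 800),
                            walk_speed = 60,
                            truth = list(), met = list(), traffic = list(),
                            start_iso = "2007-06-04") {
  tr_def <- list(wb_mean = 13.7, wb_sd = 2.3, bqe_mean = 36.7, bqe_sd = 6.5,
                 p_car_wb = 0.95, p_car_bqe = 0.90,
                 p_speed = c(slow = 0.25, med = 0.50, fast = 0.25))
  met_def <- list(wind_meanlog = log(0.9), wind_sdlog = log(3.6 / 0.9) / 1.645,
                  wind_slow = 0.7, wind_rho = 0.85, dir_sd = 15,
                  temp_mean = 26.3, temp_day_sd = 2.5, temp_pm_offset = 1.5,
                  temp_drift = 0.005, temp_noise = 0.3,
                  rh_mean = 45.8, rh_slope = -1.5, rh_noise = 4)
  truth_def <- list(
    intercept = 10.69,
    beta = c(traffic_wb = -0.029, traffic_bqe = -0.001, wind_speed = -0.046,
             temperature = 0.010, rh = 0.003),
    day_offsets = c(0, 0.10, -0.08, 0.15, 0.05, -0.12),
    ## amplitude set so the true 0-to-100-m decrement is 17.5% (the centre
    ## of the plausible near-road band for an ultrafine channel)
    decay_wb = list(form = "exp", amplitude = 0.2372, range = 60),
    decay_bqe = list(form = "exp", amplitude = 0.2372, range = 60),
    sector_only = NULL,
    spatial = data.frame(x = c(600, 650, 350), y = c(200, 720, 80),
                         amp = c(0.12, -0.10, 0.08), sd = c(100, 90, 110)),
    trend_amplitude = 0.10,
    ## coupling of the slow background to low-wind stagnation: the shared
    ## within-shift background rises when the slow wind component falls
    ## (0 = background trend independent of wind)
    trend_wind_gain = 0,
    ar = list(order = 1, phi = 0.5, sd = 0.30),
    pah = list(meanlog = log(55), sdlog = 0.80)
  )
  cfg <- list(seed = as.integer(seed), n_shifts = n_shifts,
              minutes_per_shift = minutes_per_shift,
              n_backpacks = n_backpacks, domain = domain,
              walk_speed = walk_speed,
              truth = utils::modifyList(truth_def, truth),
              met = utils::modifyList(met_def, met),
              traffic = utils::modifyList(tr_def, traffic),
              start_iso = start_iso)
  if (length(cfg$truth$ar$phi) != cfg$truth$ar$order)
    stop("AR order and phi length disagree in the truth spec")
  if (cfg$truth$ar$order > 0)
    ar_structure(cfg$truth$ar$order, cfg$truth$ar$phi)  # stationarity check
  structure(cfg, class = "scenario_config")
}

#' Named scenario presets
#'
#' * `ufp_default`: nonlinear (exponential, range 60 m) near-road decrement
#'   on both roads whose true adjusted decrease within the first 100 m lies
#'   in the 15-20% band, AR(1) noise (phi 0.5), covariate truths at the
#'   AR-model point estimates for an ultrafine-particle channel.
#' * `pm25_default`: small linear decrement (3% within 100 m, under the 5%
#'   bound), dominant day/shift background, strong meteorology effects and
#'   AR(3) noise (partial autocorrelations 0.45/0.25/0.20).
#' * `null_decay`: no distance effect at all.
#' * `sector_decay`: expressway decay present only downwind.
#'
#' @param name Preset name.
#' @param ... Overrides passed to [scenario_config()] (e.g. `seed`,
#'   `n_shifts`, `minutes_per_shift`, `n_backpacks`, or a partial `truth`
#'   list which is merged into the preset's).
#' @return A `scenario_config`.
#' @export
preset <- function(name = c("ufp_default", "pm25_default", "null_decay",
                            "sector_decay"), ...) {
  name <- match.arg(name)
  over <- list(...)
  truth <- switch(name,
    ufp_default = list(),
    pm25_default = list(
      intercept = 2.70,
      beta = c(traffic_wb = 0.012, traffic_bqe = 0.004, wind_speed = -0.071,
               temperature = 0.033, rh = 0.015),
      day_offsets = c(0, 0.50, -0.40, 0.60, 0.20, -0.50),
      decay_wb = list(form = "linear", slope = 3.05e-4, max_d = 500),
      decay_bqe = list(form = "linear", slope = 3.05e-4, max_d = 500),
      trend_amplitude = 0.25,
      ar = list(order = 3, phi = c(0.2875, 0.1825, 0.2), sd = 0.20)),
    null_decay = list(
      decay_wb = list(form = "exp", amplitude = 0, range = 60),
      decay_bqe = list(form = "exp", amplitude = 0, range = 60)),
    sector_decay = list(sector_only = "bqe")
  )
  if (!is.null(over$truth)) {
    truth <- utils::modifyList(truth, over$truth)
    over$truth <- NULL
  }
  cfg <- do.call(scenario_config, c(list(truth = truth), over))
  cfg$preset <- name
  cfg$pollutant <- if (name == "pm25_default") "pm25" else "ufp"
  cfg
}

## truth decay value (log-units, >= 0 near the road) at distance d
decay_value <- function(spec, d) {
  switch(spec$form,
         exp = spec$amplitude * exp(-d / spec$range),
         linear = -spec$slope * pmin(d, spec$max_d),
         stop("unknown decay form '", spec$form, "'"))
}

#' True adjusted percent decrease between two distances
#'
#' `100 * (1 - exp(f(to) - f(from)))` for a preset's decay component —
#' the ground-truth analogue of the `pct_decrease_100m` summary.
#'
#' @param config A `scenario_config`.
#' @param road `"wb"` or `"bqe"`.
#' @param from,to Distances in metres (defaults: road edge 0 m to 100 m).
#' @return Percent decrease.
#' @export
true_pct_decrease <- function(config, road = "bqe", from = 0, to = 100) {
  spec <- config$truth[[paste0("decay_", road)]]
  100 * (1 - exp(decay_value(spec, to) - decay_value(spec, from)))
}

## default road layout: an at-grade N-S expressway and an E-W bridge whose
## deck ramps from ground level to 40 m
default_roads <- function(domain) {
  list(
    wb = road_source("WB",
                     rbind(c(domain[1], 550), c(400, 550), c(domain[2], 550)),
                     elevation = c(0, 40, 40),
                     counter_ids = c("wb_n", "wb_s")),
    bqe = road_source("BQE",
                      rbind(c(150, domain[3]), c(150, domain[4])),
                      elevation = c(0, 0),
                      counter_ids = c("bqe_1", "bqe_2", "bqe_3"))
  )
}

## stationary AR(p) series of length n with given innovation sd
sim_ar <- function(n, order, phi, sd) {
  if (order == 0) return(stats::rnorm(n, 0, sd))
  burn <- 50 + 10 * order
  e <- stats::rnorm(n + burn, 0, sd)
  x <- numeric(n + burn)
  for (t in seq_len(n + burn)) {
    acc <- e[t]
    for (k in seq_len(min(order, t - 1))) acc <- acc + phi[k] * x[t - k]
    x[t] <- acc
  }
  x[(burn + 1):(burn + n)]
}

## Waypoint walk at 1-min resolution. Scripted routes covered every street
## with emphasis on the source corridors, so waypoints are a mixture:
## with probability `p_road` the next waypoint sits in a 150-m strip along
## one of the roads, otherwise anywhere in the domain.
sim_route <- function(n_min, domain, speed, roads = NULL, p_road = 0.5) {
  draw_waypoint <- function() {
    if (!is.null(roads) && stats::runif(1) < p_road) {
      rd <- roads[[sample(length(roads), 1)]]
      s <- stats::runif(1, 0, road_length(rd))
      pt <- point_at_arclength(rd, s)
      off <- stats::runif(2, -150, 150)
      c(min(max(pt$x + off[1], domain[1]), domain[2]),
        min(max(pt$y + off[2], domain[3]), domain[4]))
    } else {
      c(stats::runif(1, domain[1], domain[2]),
        stats::runif(1, domain[3], domain[4]))
    }
  }
  pos <- matrix(NA_real_, n_min, 2)
  cur <- draw_waypoint()
  target <- draw_waypoint()
  for (i in seq_len(n_min)) {
    v <- target - cur
    dst <- sqrt(sum(v^2))
    while (dst < speed) {  # reached the waypoint this minute: pick a new one
      target <- draw_waypoint()
      v <- target - cur
      dst <- sqrt(sum(v^2))
    }
    cur <- cur + v / dst * speed
    pos[i, ] <- cur
  }
  pos
}

#' Generate a complete synthetic campaign
#'
#' Simulates routes, meteorology, traffic and per-minute log concentrations
#' assembled from the documented truth components
#' (`y = intercept + day + shift trend + X beta + f_WB + f_BQE + f_s + AR
#' noise`), and returns every stream in the covariate-module formats along
#' with the truth.
#'
#' @param config A [scenario_config()] or [preset()].
#' @return List of class `campaign`: `observations`, `traffic` (15-min
#'   intervals), `weather`, `roads` (list of [road_source()]), `sessions`
#'   (shift windows), `truth` (config parameters plus the per-row
#'   `components` data frame), `config`.
#' @export
generate_campaign <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  tr <- config$truth; met <- config$met; tcf <- config$traffic
  roads <- default_roads(config$domain)
  n_days <- ceiling(config$n_shifts / 2)
  day0 <- minute_index(paste0(config$start_iso, "T00:00:00Z"))

  ## ---- schedule ----
  sessions <- do.call(rbind, lapply(seq_len(config$n_shifts), function(s) {
    day <- (s - 1) %/% 2 + 1
    hour <- if (s %% 2 == 1) 9 else 14
    start <- day0 + (day - 1) * 1440 + hour * 60
    data.frame(shift_id = sprintf("d%02ds%d", day, 2 - s %% 2),
               day_id = sprintf("d%02d", day),
               start = start, end = start + config$minutes_per_shift - 1,
               afternoon = hour >= 12)
  }))
  shift_phase <- stats::runif(config$n_shifts, 0, 2 * pi)

  ## ---- weather (one fixed station) ----
  weather <- do.call(rbind, lapply(seq_len(config$n_shifts), function(s) {
    n <- config$minutes_per_shift
    ## log wind = slow within-shift swing (gust fronts, sea-breeze ramps)
    ## + minute-scale AR(1) noise; total log-scale variance kept at the
    ## campaign calibration (median 0.9, 95th pct 3.6 m/s)
    slow <- met$wind_slow *
      sin(2 * pi * (0:(n - 1)) / n + stats::runif(1, 0, 2 * pi))
    fast_sd <- sqrt(max(met$wind_sdlog^2 - met$wind_slow^2 / 2, 0.01))
    z <- sim_ar(n, 1, met$wind_rho, sqrt(1 - met$wind_rho^2))
    ws <- exp(met$wind_meanlog + slow + fast_sd * z)
    base_dir <- stats::runif(1, 0, 360)
    wd <- (base_dir + cumsum(stats::rnorm(n, 0, met$dir_sd)) * 0.3) %% 360
    data.frame(minute = sessions$start[s] + 0:(n - 1),
               wind_speed = ws, wind_dir = wd, slow_log = slow)
  }))

  ## ---- traffic: 15-min intervals per counter covering each session ----
  traffic <- do.call(rbind, lapply(seq_len(config$n_shifts), function(s) {
    t0 <- (sessions$start[s] %/% 15) * 15
    t1 <- sessions$end[s]
    starts <- seq(t0, t1, by = 15)
    out <- list()
    for (role in names(roads)) {
      rd <- roads[[role]]
      mu <- if (role == "wb") tcf$wb_mean else tcf$bqe_mean
      sdv <- if (role == "wb") tcf$wb_sd else tcf$bqe_sd
      pcar <- if (role == "wb") tcf$p_car_wb else tcf$p_car_bqe
      nc <- length(rd$counter_ids)
      tot_road <- pmax(0, round(stats::rnorm(length(starts), mu * 15, sdv * 15)))
      ## even split across the road's counters (remainder to the first ones)
      base <- tot_road %/% nc
      for (ci in seq_len(nc)) {
        tot <- base + as.integer(ci <= (tot_road %% nc))
        car <- stats::rbinom(length(tot), tot, pcar)
        spd <- vapply(tot, function(m)
          as.integer(stats::rmultinom(1, m, tcf$p_speed)), integer(3))
        out[[paste(role, ci)]] <- data.frame(
          counter_id = rd$counter_ids[ci], start = starts, duration = 15L,
          count_total = tot, count_car = car, count_truckbus = tot - car,
          count_slow = spd[1, ], count_med = spd[2, ], count_fast = spd[3, ])
      }
    }
    do.call(rbind, out)
  }))
  rownames(traffic) <- NULL
  traffic_min <- disaggregate_traffic(traffic)

  ## per-minute road totals (the covariate the truth uses)
  road_total <- function(role) {
    ids <- roads[[role]]$counter_ids
    sub <- traffic_min[traffic_min$counter_id %in% ids, ]
    stats::aggregate(list(total = sub$total), by = list(minute = sub$minute),
                     FUN = sum)
  }
  twb <- road_total("wb"); tbqe <- road_total("bqe")

  ## ---- observations ----
  obs_list <- list(); comp_list <- list()
  for (s in seq_len(config$n_shifts)) {
    n <- config$minutes_per_shift
    mins <- sessions$start[s] + 0:(n - 1)
    ## shared ambient temperature / RH for the shift
    tday <- stats::rnorm(1, met$temp_mean, met$temp_day_sd)
    temp <- tday + (sessions$afternoon[s]) * met$temp_pm_offset +
      met$temp_drift * (0:(n - 1)) + sim_ar(n, 1, 0.8, met$temp_noise)
    rh <- met$rh_mean + met$rh_slope * (temp - met$temp_mean) +
      sim_ar(n, 1, 0.8, met$rh_noise)
    rh <- pmin(95, pmax(5, rh))
    widx <- match(mins, weather$minute)
    ws <- weather$wind_speed[widx]; wd <- weather$wind_dir[widx]
    trend <- tr$trend_amplitude * sin(2 * pi * (0:(n - 1)) / n + shift_phase[s]) -
      tr$trend_wind_gain * weather$slow_log[widx]
    day <- (s - 1) %/% 2 + 1
    dayoff <- rep_len(tr$day_offsets, n_days)[day]
    t_wb <- twb$total[match(mins, twb$minute)]
    t_bqe <- tbqe$total[match(mins, tbqe$minute)]

    for (b in seq_len(config$n_backpacks)) {
      pos <- sim_route(n, config$domain, config$walk_speed, roads = roads)
      d_wb <- effective_distance(pos, roads$wb)
      d_bqe <- nearest_distance(pos, roads$bqe)
      f_wb <- decay_value(tr$decay_wb, d_wb)
      f_bqe <- decay_value(tr$decay_bqe, d_bqe)
      if (!is.null(tr$sector_only)) {
        gate <- function(role, f) {
          sec <- wind_sector(pos, roads[[role]], wd, ws)
          ifelse(sec == "downwind", f, 0)
        }
        if ("wb" %in% tr$sector_only) f_wb <- gate("wb", f_wb)
        if ("bqe" %in% tr$sector_only) f_bqe <- gate("bqe", f_bqe)
      }
      f_s <- rep(0, n)
      for (i in seq_len(nrow(tr$spatial)))
        f_s <- f_s + tr$spatial$amp[i] *
          exp(-((pos[, 1] - tr$spatial$x[i])^2 +
                (pos[, 2] - tr$spatial$y[i])^2) / (2 * tr$spatial$sd[i]^2))
      xbeta <- tr$beta[["traffic_wb"]] * t_wb +
        tr$beta[["traffic_bqe"]] * t_bqe +
        tr$beta[["wind_speed"]] * ws +
        tr$beta[["temperature"]] * temp + tr$beta[["rh"]] * rh
      noise <- sim_ar(n, tr$ar$order, tr$ar$phi, tr$ar$sd)
      y <- tr$intercept + dayoff + trend + xbeta + f_wb + f_bqe + f_s + noise
      key <- sprintf("%s_b%d", sessions$shift_id[s], b)
      obs_list[[key]] <- data.frame(
        minute = mins, easting = pos[, 1], northing = pos[, 2],
        shift_id = sessions$shift_id[s], day_id = sessions$day_id[s],
        operator_id = sprintf("bp%d", b),
        ufp = if (config$pollutant %||% "ufp" == "ufp") exp(y) else
          exp(stats::rnorm(n, 10.6, 0.5)),
        pm25 = if (identical(config$pollutant, "pm25")) exp(y) else
          exp(stats::rnorm(n, 3.4, 0.4)),
        pah = exp(stats::rnorm(n, tr$pah$meanlog, tr$pah$sdlog)),
        temperature = temp, rh = rh, stringsAsFactors = FALSE)
      comp_list[[key]] <- data.frame(
        minute = mins, operator_id = sprintf("bp%d", b), y = y,
        intercept = tr$intercept, day_offset = dayoff, trend = trend,
        xbeta = xbeta, f_wb = f_wb, f_bqe = f_bqe, f_s = f_s, noise = noise)
    }
  }
  observations <- do.call(rbind, obs_list)
  components <- do.call(rbind, comp_list)
  rownames(observations) <- rownames(components) <- NULL

  truth <- list(preset = config$preset %||% "custom",
                pollutant = config$pollutant %||% "ufp",
                intercept = tr$intercept, beta = as.list(tr$beta),
                day_offsets = rep_len(tr$day_offsets, n_days),
                decay_wb = tr$decay_wb, decay_bqe = tr$decay_bqe,
                sector_only = tr$sector_only,
                trend_amplitude = tr$trend_amplitude,
                trend_wind_gain = tr$trend_wind_gain,
                ar = tr$ar,
                true_pct_decrease_100m = list(
                  wb = true_pct_decrease(config, "wb"),
                  bqe = true_pct_decrease(config, "bqe")),
                components = components)

  structure(list(observations = observations, traffic = traffic,
                 weather = weather, roads = roads, sessions = sessions,
                 truth = truth, config = config),
            class = "campaign")
}

#' @export
print.campaign <- function(x, ...) {
  cat(sprintf("campaign '%s': %d obs rows, %d shifts x %d backpacks, pollutant %s\n",
              x$truth$preset, nrow(x$observations), x$config$n_shifts,
              x$config$n_backpacks, x$truth$pollutant))
  invisible(x)
}

#' Build the modelling frame for a campaign
#'
#' Convenience wrapper: QC filter, traffic disaggregation and
#' [build_model_frame()] with the campaign's roads, plus the per-road
#' vehicle-class and speed traffic columns used by the sensitivity refits.
#'
#' @param campaign A [generate_campaign()] result.
#' @param pollutant Default: the campaign's own pollutant.
#' @return A `model_frame`.
#' @export
campaign_frame <- function(campaign, pollutant = campaign$truth$pollutant) {
  qc <- qc_filter(campaign$observations, campaign$sessions)
  tmin <- disaggregate_traffic(campaign$traffic)
  fr <- build_model_frame(qc$observations, tmin, campaign$weather,
                          campaign$roads$wb, campaign$roads$bqe,
                          pollutant = pollutant)
  ## add class/speed per-road splits for the sensitivity analyses
  for (role in c("wb", "bqe")) {
    ids <- campaign$roads[[role]]$counter_ids
    sub <- tmin[tmin$counter_id %in% ids, ]
    for (col in c("car", "truckbus", "slow", "med", "fast")) {
      agg <- stats::aggregate(list(v = sub[[col]]),
                              by = list(minute = sub$minute), FUN = sum)
      fr[[paste0("traffic_", role, "_", col)]] <-
        agg$v[match(fr$minute, agg$minute)]
    }
  }
  fr
}

## groups within which AR correlation is coherent: one backpack's route in
## one shift
ar_groups <- function(frame) paste(frame$shift_id, frame$operator_id)

#' Write a campaign to disk in the exchange formats
#'
#' `observations.csv`, `traffic.csv`, `weather.csv`, `sessions.csv`,
#' `roads.geojson` and `truth.json` (scenario parameters and true component
#' summaries; the per-row components go to `truth_components.csv`).
#'
#' @param campaign A [generate_campaign()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_campaign <- function(campaign, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  o <- campaign$observations
  utils::write.csv(data.frame(
    timestamp_iso = minute_iso(o$minute), easting_m = o$easting,
    northing_m = o$northing, shift_id = o$shift_id, day_id = o$day_id,
    operator_id = o$operator_id, ufp_pcc = o$ufp, pm25_ugm3 = o$pm25,
    pah_ngm3 = o$pah, temp_c = o$temperature, rh_pct = o$rh),
    file.path(dir, "observations.csv"), row.names = FALSE)
  tr <- campaign$traffic
  utils::write.csv(data.frame(
    counter_id = tr$counter_id, start_iso = minute_iso(tr$start),
    count_total = tr$count_total, count_car = tr$count_car,
    count_truckbus = tr$count_truckbus, count_slow = tr$count_slow,
    count_med = tr$count_med, count_fast = tr$count_fast),
    file.path(dir, "traffic.csv"), row.names = FALSE)
  w <- campaign$weather
  utils::write.csv(data.frame(
    timestamp_iso = minute_iso(w$minute), wind_speed_ms = w$wind_speed,
    wind_dir_deg = w$wind_dir),
    file.path(dir, "weather.csv"), row.names = FALSE)
  utils::write.csv(campaign$sessions, file.path(dir, "sessions.csv"),
                   row.names = FALSE)
  write_roads_geojson(campaign$roads, file.path(dir, "roads.geojson"))
  tj <- campaign$truth
  utils::write.csv(tj$components, file.path(dir, "truth_components.csv"),
                   row.names = FALSE)
  tj$components <- NULL
  jsonlite::write_json(tj, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}
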