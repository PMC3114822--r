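## Covariate assembly: traffic disaggregation, QC filtering, stream joins and
## the per-minute modelling frame.
##
## Internally every stream is keyed by an integer absolute minute index
## (minutes since 1970-01-01 00:00 UTC); the CSV interfaces use ISO-8601
## timestamps and are converted on read/write.

#' Convert ISO-8601 timestamps to absolute minute indices
#' @param x Character vector of timestamps (UTC assumed).
#' @return Integer minutes since 1970-01-01 00:00 UTC.
#' @export
minute_index <- function(x) {
  t <- as.POSIXct(x, tz = "UTC",
                  tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                                 "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d"))
  as.integer(round(as.numeric(t) / 60))
}

#' Convert absolute minute indices back to ISO-8601 strings (UTC)
#' @param m Integer minute indices.
#' @return Character vector.
#' @export
minute_iso <- function(m) {
  format(as.POSIXct(as.numeric(m) * 60, origin = "1970-01-01", tz = "UTC"),
         "%Y-%m-%dT%H:%M:%SZ")
}

#' Disaggregate 15-min traffic counts to the 1-min scale
#'
#' Each minute within a counting interval receives 1/15th of the interval
#' count (fractional values allowed), for the total and every sub-category,
#' under the assumption of uniform traffic volume within the interval.
#' Minutes not covered by any interval are simply absent from the result
#' (downstream joins treat them as missing).
#'
#' @param intervals Data frame with columns `counter_id`, `start` (absolute
#'   minute index of the interval start), `duration` (minutes, default 15
#'   when absent) and count columns `count_total`, `count_car`,
#'   `count_truckbus`, `count_slow`, `count_med`, `count_fast` (missing count
#'   columns are skipped).
#' @return Data frame with columns `counter_id`, `minute` and per-minute
#'   values `total`, `car`, `truckbus`, `slow`, `med`, `fast` (those present).
#' @export
disaggregate_traffic <- function(intervals) {
  if (is.null(intervals$duration)) intervals$duration <- 15L
  cnt_cols <- intersect(c("count_total", "count_car", "count_truckbus",
                          "count_slow", "count_med", "count_fast"),
                        names(intervals))
  ## overlap check per counter
  for (cid in unique(intervals$counter_id)) {
    iv <- intervals[intervals$counter_id == cid, ]
    iv <- iv[order(iv$start), ]
    if (nrow(iv) > 1 &&
        any(iv$start[-1] < (iv$start[-nrow(iv)] + iv$duration[-nrow(iv)])))
      stop("overlapping traffic intervals for counter '", cid, "'")
  }
  idx <- rep(seq_len(nrow(intervals)), intervals$duration)
  off <- sequence(intervals$duration) - 1L
  out <- data.frame(counter_id = intervals$counter_id[idx],
                    minute = intervals$start[idx] + off)
  for (cc in cnt_cols) {
    nm <- sub("^count_", "", cc)
    out[[nm]] <- intervals[[cc]][idx] / intervals$duration[idx]
  }
  out
}

#' Quality-control filter for mobile observations
#'
#' Removes rows timestamped outside their shift's session window and rows
#' with any pollutant reading below its configured floor (abnormally low
#' instrument readings). A warning is emitted if more than `warn_fraction`
#' of rows are excluded.
#'
#' @param observations Data frame with at least `minute`, `shift_id` and the
#'   pollutant columns named in `floors`.
#' @param sessions Data frame `shift_id`, `start`, `end` (absolute minutes,
#'   inclusive window).
#' @param floors Named list of lower bounds per pollutant column; defaults
#'   `ufp = 1000` particles/cm3, `pm25 = 1` ug/m3.
#' @param warn_fraction Warn when the excluded fraction exceeds this
#'   (default 0.05).
#' @return List with `observations` (kept rows) and `report`, a data frame
#'   `reason` / `n_removed` (reasons `outside_session` then `low_reading`;
#'   a row excluded for being outside its session is not double-counted).
#' @export
qc_filter <- function(observations, sessions,
                      floors = list(ufp = 1000, pm25 = 1),
                      warn_fraction = 0.05) {
  m <- match(observations$shift_id, sessions$shift_id)
  if (anyNA(m)) stop("observations reference unknown shift_id(s)")
  outside <- observations$minute < sessions$start[m] |
    observations$minute > sessions$end[m]
  low <- rep(FALSE, nrow(observations))
  for (p in names(floors)) {
    if (!is.null(observations[[p]]))
      low <- low | (!is.na(observations[[p]]) & observations[[p]] < floors[[p]])
  }
  low <- low & !outside
  report <- data.frame(reason = c("outside_session", "low_reading"),
                       n_removed = c(sum(outside), sum(low)))
  report <- report[report$n_removed > 0, , drop = FALSE]
  frac <- (sum(outside) + sum(low)) / max(1L, nrow(observations))
  if (frac > warn_fraction)
    warning(sprintf("qc_filter excluded %.1f%% of rows (> %.0f%%)",
                    100 * frac, 100 * warn_fraction))
  list(observations = observations[!(outside | low), , drop = FALSE],
       report = report, fraction_excluded = frac)
}

#' Assemble the per-minute modelling frame
#'
#' Joins the observation, traffic and weather streams on the absolute minute,
#' computes log concentration and the distance, wind-sector and time-in-shift
#' covariates. Distances to the elevated road (`road_wb`) use
#' [effective_distance()]; distances to the at-grade road (`road_bqe`) use
#' [nearest_distance()]. Per-road traffic is the sum of the per-minute series
#' of the counters listed in each road's `counter_ids`. Rows whose minute is
#' missing from any required stream are dropped (the count is reported in the
#' `dropped` attribute).
#'
#' @param observations QC-filtered observation data frame (`minute`,
#'   `easting`, `northing`, `shift_id`, `day_id`, `operator_id`, pollutant
#'   columns, `temperature`, `rh`).
#' @param traffic Per-minute traffic from [disaggregate_traffic()].
#' @param weather Data frame `minute`, `wind_speed`, `wind_dir`.
#' @param road_wb,road_bqe [road_source()] objects for the elevated and
#'   at-grade line sources.
#' @param pollutant One of `"ufp"`, `"pm25"`, `"pah"`.
#' @return Data frame of class `model_frame` with columns `y` (natural-log
#'   concentration), `conc`, `traffic_wb`, `traffic_bqe`, `wind_speed`,
#'   `temperature`, `rh`, `day_id`, `shift_id`, `operator_id`, `d_wb`,
#'   `d_bqe`, `easting`, `northing`, `t_shift`, `sector_wb`, `sector_bqe`,
#'   `minute`; sorted by minute then operator. Attributes: `pollutant`,
#'   `dropped` (rows lost in the join).
#' @export
build_model_frame <- function(observations, traffic, weather,
                              road_wb, road_bqe, pollutant = "ufp") {
  pollutant <- match.arg(pollutant, c("ufp", "pm25", "pah"))
  obs <- observations[!is.na(observations[[pollutant]]), , drop = FALSE]
  if (any(obs[[pollutant]] <= 0))
    stop("pollutant readings must be strictly positive for the log transform")

  road_traffic <- function(road) {
    tr <- traffic[traffic$counter_id %in% road$counter_ids, , drop = FALSE]
    agg <- stats::aggregate(list(total = tr$total), by = list(minute = tr$minute),
                            FUN = sum)
    n_ctr <- stats::aggregate(list(n = tr$total), by = list(minute = tr$minute),
                              FUN = length)
    ## a minute is covered only if every configured counter reported
    agg$total[n_ctr$n < length(road$counter_ids)] <- NA
    agg
  }
  twb <- road_traffic(road_wb)
  tbqe <- road_traffic(road_bqe)

  mwb <- match(obs$minute, twb$minute)
  mbqe <- match(obs$minute, tbqe$minute)
  mw <- match(obs$minute, weather$minute)
  keep <- !is.na(mwb) & !is.na(mbqe) & !is.na(mw) &
    !is.na(twb$total[mwb]) & !is.na(tbqe$total[mbqe]) &
    !is.na(weather$wind_speed[mw])
  dropped <- sum(!keep)
  if (!any(keep)) stop("empty join: observation minutes match no traffic/weather minutes (misaligned clocks?)")
  obs <- obs[keep, , drop = FALSE]
  mwb <- mwb[keep]; mbqe <- mbqe[keep]; mw <- mw[keep]

  pts <- cbind(obs$easting, obs$northing)
  wdir <- weather$wind_dir[mw]
  wspd <- weather$wind_speed[mw]

  frame <- data.frame(
    minute = obs$minute,
    y = log(obs[[pollutant]]),
    conc = obs[[pollutant]],
    traffic_wb = twb$total[mwb],
    traffic_bqe = tbqe$total[mbqe],
    wind_speed = wspd,
    temperature = obs$temperature,
    rh = obs$rh,
    day_id = factor(obs$day_id),
    shift_id = factor(obs$shift_id),
    operator_id = obs$operator_id,
    d_wb = effective_distance(pts, road_wb),
    d_bqe = nearest_distance(pts, road_bqe),
    easting = obs$easting,
    northing = obs$northing,
    sector_wb = wind_sector(pts, road_wb, wdir, wspd),
    sector_bqe = wind_sector(pts, road_bqe, wdir, wspd),
    stringsAsFactors = FALSE
  )
  shift_start <- tapply(frame$minute, frame$shift_id, min)
  frame$t_shift <- frame$minute - as.numeric(shift_start[as.character(frame$shift_id)])
  ord <- order(frame$minute, frame$operator_id)
  frame <- frame[ord, , drop = FALSE]
  rownames(frame) <- NULL
  structure(frame, pollutant = pollutant, dropped = dropped,
            class = c("model_frame", "data.frame"))
}

#' High/low flag by median split
#'
#' `TRUE` where the value strictly exceeds the column median; ties go to the
#' low stratum.
#'
#' @param frame Data frame.
#' @param column Column name to split on.
#' @return Logical vector.
#' @export
median_split <- function(frame, column) {
  v <- frame[[column]]
  if (is.null(v)) stop("no column '", column, "'")
  if (anyNA(v)) stop("'", column, "' has missing values")
  v > stats::median(v)
}

## ---- CSV dialects --------------------------------------------------------

#' Read/write the campaign CSV dialects
#'
#' Columns: observations `timestamp_iso, easting_m, northing_m, shift_id,
#' day_id, operator_id, ufp_pcc, pm25_ugm3, pah_ngm3, temp_c, rh_pct`;
#' traffic `counter_id, start_iso, count_total, count_car, count_truckbus,
#' count_slow, count_med, count_fast`; weather `timestamp_iso, wind_speed_ms,
#' wind_dir_deg`.
#'
#' @param path CSV path.
#' @return Data frame in the internal (minute-indexed) naming.
#' @export
read_observations_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(minute = minute_index(d$timestamp_iso),
             easting = d$easting_m, northing = d$northing_m,
             shift_id = d$shift_id, day_id = d$day_id,
             operator_id = d$operator_id,
             ufp = d$ufp_pcc, pm25 = d$pm25_ugm3, pah = d$pah_ngm3,
             temperature = d$temp_c, rh = d$rh_pct,
             stringsAsFactors = FALSE)
}

#' @rdname read_observations_csv
#' @export
read_traffic_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$start <- minute_index(d$start_iso)
  d$start_iso <- NULL
  d
}

#' @rdname read_observations_csv
#' @export
read_weather_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(minute = minute_index(d$timestamp_iso),
             wind_speed = d$wind_speed_ms, wind_dir = d$wind_dir_deg)
}
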