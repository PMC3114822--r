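test_that("traffic disaggregation spreads 1/15th per minute and conserves totals", {
  iv <- data.frame(counter_id = "c1", start = 0L, duration = 15L,
                   count_total = 30, count_car = 27, count_truckbus = 3)
  pm <- disaggregate_traffic(iv)
  expect_equal(nrow(pm), 15)
  expect_true(all(pm$total == 2.0))
  expect_true(all(pm$car == 1.8))
  expect_equal(sum(pm$total), 30)

  iv0 <- data.frame(counter_id = "c1", start = 0L, count_total = 0)
  expect_true(all(disaggregate_traffic(iv0)$total == 0))

  ## conservation with awkward counts, multiple counters and intervals
  set.seed(5)
  iv2 <- data.frame(counter_id = rep(c("a", "b"), each = 4),
                    start = rep(seq(0, 45, 15), 2),
                    count_total = rpois(8, 40))
  pm2 <- disaggregate_traffic(iv2)
  tot <- tapply(pm2$total, pm2$counter_id, sum)
  expect_equal(as.numeric(tot), as.numeric(tapply(iv2$count_total, iv2$counter_id, sum)),
               tolerance = 1e-9)

  ov <- data.frame(counter_id = "a", start = c(0L, 10L), count_total = c(1, 2))
  expect_error(disaggregate_traffic(ov), "overlapping")
})

test_that("QC filter removes out-of-session and low readings with a partitioned report", {
  sessions <- data.frame(shift_id = "s1", start = 100L, end = 110L)
  obs <- data.frame(minute = c(95L, 100L, 105L, 110L, 111L),
                    shift_id = "s1",
                    ufp = c(5e4, 500, 4e4, 4.4e4, 4e4),
                    pm25 = c(30, 30, 30, 30, 30))
  out <- suppressWarnings(qc_filter(obs, sessions))
  expect_equal(nrow(out$observations), 2)  # minutes 105 and 110 survive
  expect_equal(out$report$n_removed[out$report$reason == "outside_session"], 2)
  expect_equal(out$report$n_removed[out$report$reason == "low_reading"], 1)
  ## reasons partition the removed set
  expect_equal(sum(out$report$n_removed), nrow(obs) - nrow(out$observations))

  clean <- data.frame(minute = 100:110, shift_id = "s1", ufp = 4e4, pm25 = 30)
  res <- qc_filter(clean, sessions)
  expect_identical(res$observations, clean)
  expect_equal(nrow(res$report), 0)
})

test_that("QC filter warns when the excluded fraction exceeds the threshold", {
  sessions <- data.frame(shift_id = "s1", start = 100L, end = 200L)
  obs <- data.frame(minute = c(10L, rep(150L, 9)), shift_id = "s1",
                    ufp = 4e4, pm25 = 30)
  expect_warning(qc_filter(obs, sessions), "excluded 10")
  expect_silent(qc_filter(obs, sessions, warn_fraction = 0.5))
})

test_that("model frame joins streams, log-transforms and attaches distances", {
  cmp <- small_campaign(seed = 21)
  fr <- campaign_frame(cmp)
  expect_s3_class(fr, "model_frame")
  expect_true(all(is.finite(fr$y)))
  expect_equal(fr$y, log(fr$conc))
  expect_true(all(fr$d_wb >= 0 & fr$d_bqe >= 0))
  ## ln(44000) reference value
  i <- which.min(abs(fr$conc - 44000))
  expect_equal(fr$y[i], log(fr$conc[i]))
  expect_equal(log(44000), 10.6919, tolerance = 1e-4)

  ## effective distance is used for the elevated road
  pts <- cbind(fr$easting, fr$northing)
  expect_equal(fr$d_wb, effective_distance(pts, cmp$roads$wb))
  expect_equal(fr$d_bqe, nearest_distance(pts, cmp$roads$bqe))
  expect_true(all(fr$d_wb >= nearest_distance(pts, cmp$roads$wb) - 1e-12))

  ## idempotent re-build with identical row order
  fr2 <- campaign_frame(cmp)
  expect_identical(fr, fr2)
  expect_false(is.unsorted(fr$minute))
})

test_that("rows with uncovered minutes are dropped and counted", {
  cmp <- small_campaign(seed = 22)
  tmin <- disaggregate_traffic(cmp$traffic)
  qc <- qc_filter(cmp$observations, cmp$sessions)
  ## remove traffic coverage of one counter for the first 30 minutes
  drop_min <- sort(unique(tmin$minute))[1:30]
  tcut <- tmin[!(tmin$minute %in% drop_min & tmin$counter_id == "bqe_1"), ]
  fr <- build_model_frame(qc$observations, tcut, cmp$weather,
                          cmp$roads$wb, cmp$roads$bqe)
  full <- build_model_frame(qc$observations, tmin, cmp$weather,
                            cmp$roads$wb, cmp$roads$bqe)
  expect_lt(nrow(fr), nrow(full))
  expect_equal(attr(fr, "dropped") - attr(full, "dropped"),
               nrow(full) - nrow(fr))

  ## fully misaligned clocks -> error
  wshift <- cmp$weather
  wshift$minute <- wshift$minute + 1e6
  expect_error(build_model_frame(qc$observations, tmin, wshift,
                                 cmp$roads$wb, cmp$roads$bqe),
               "misaligned")
})

test_that("median split sends ties to the low stratum", {
  fr <- data.frame(v = c(1, 2, 3, 4, 5))
  expect_equal(median_split(fr, "v"), c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_true(all(!median_split(data.frame(v = rep(7, 10)), "v")))
  set.seed(1)
  for (i in 1:10) {
    fr <- data.frame(v = rnorm(101))
    hi <- median_split(fr, "v")
    expect_true(any(hi) && any(!hi))  # non-constant -> two non-empty strata
  }
  expect_error(median_split(fr, "nope"), "no column")
})

test_that("campaign CSV dialects round-trip through the readers", {
  cmp <- small_campaign(seed = 23)
  d <- tempfile()
  write_campaign(cmp, d)
  obs <- read_observations_csv(file.path(d, "observations.csv"))
  expect_equal(nrow(obs), nrow(cmp$observations))
  expect_equal(obs$minute, cmp$observations$minute)
  expect_equal(obs$ufp, cmp$observations$ufp, tolerance = 1e-12)
  tr <- read_traffic_csv(file.path(d, "traffic.csv"))
  expect_equal(tr$start, cmp$traffic$start)
  w <- read_weather_csv(file.path(d, "weather.csv"))
  expect_equal(w$wind_speed, cmp$weather$wind_speed, tolerance = 1e-12)
  unlink(d, recursive = TRUE)
})
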