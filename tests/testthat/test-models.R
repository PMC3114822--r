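test_that("AR order selection identifies white noise and known AR structures", {
  set.seed(31)
  shifts <- rep(1:10, each = 500)
  ## white noise
  hits0 <- 0
  for (i in 1:10) {
    r <- rnorm(5000)
    hits0 <- hits0 + (select_ar_order(r, shifts)$order == 0)
  }
  expect_gte(hits0, 9)

  ## AR(1) phi = 0.6
  phis <- numeric(5)
  for (i in 1:5) {
    r <- as.numeric(vapply(1:10, function(s) mobilegam:::sim_ar(500, 1, 0.6, 1),
                           numeric(500)))
    sel <- select_ar_order(r, shifts)
    expect_equal(sel$order, 1)
    phis[i] <- sel$phi
  }
  expect_lt(max(abs(phis - 0.6)), 0.05)

  ## AR(3) with the pm25 preset's coefficients
  phi3 <- preset("pm25_default")$truth$ar$phi
  for (i in 1:3) {
    r <- as.numeric(vapply(1:10, function(s) mobilegam:::sim_ar(500, 3, phi3, 1),
                           numeric(500)))
    sel <- select_ar_order(r, shifts)
    expect_equal(sel$order, 3)
    expect_lt(max(abs(sel$phi - phi3)), 0.08)
  }

  expect_error(select_ar_order(rnorm(30), rep(1:6, each = 5), p_max = 5),
               "shorter")
})

test_that("the AR refit reduces to the additive fit when errors are independent", {
  fr <- small_frame(seed = 33, truth = list(ar = list(order = 0,
                                                      phi = numeric(0),
                                                      sd = 0.3)))
  fa <- fit_additive(fr)
  far <- fit_ar(fr)
  if (far$ar$order == 0) {
    expect_equal(far$fit$beta, fa$fit$beta, tolerance = 1e-12)
  } else {
    ## order selected spuriously small phi: coefficients agree within 1 SE
    idx <- fa$fit$blocks$parametric
    se <- sqrt(diag(fa$fit$Vp)[idx])
    expect_true(all(abs(far$fit$beta[idx] - fa$fit$beta[idx]) < se))
  }
})

test_that("distance curves recentre at the reference and expose the percent summary", {
  fr <- small_frame(seed = 34)
  fa <- fit_additive(fr)
  cur <- fa$curves$BQE
  expect_equal(cur$eta[1], 0)
  expect_true(all(cur$lo95 <= cur$eta + 1e-12 & cur$eta <= cur$hi95 + 1e-12))
  ## the summary is the algebraic transform of eta(100)
  eta100 <- approx(cur$distance, cur$eta, 100)$y
  expect_equal(attr(cur, "pct_decrease_100m"), 100 * (1 - exp(eta100)))
  ## a flat (all-zero) smooth gives exactly 0% decrease
  flat <- fa
  flat$fit$beta[flat$fit$blocks$f_BQE] <- 0
  cflat <- predict_distance_curve(flat, "BQE")
  expect_identical(attr(cflat, "pct_decrease_100m"), 0)
  ## grid truncation warns rather than extrapolates
  expect_warning(predict_distance_curve(fa, "BQE",
                                        grid = c(1, 50, 100, 5000)),
                 "truncated")
})

test_that("time-trend model needs >= 2 shifts and matches the AR model absent a trend", {
  fr <- small_frame(seed = 35, truth = list(trend_amplitude = 0))
  one <- fr[fr$shift_id == fr$shift_id[1], ]
  class(one) <- class(fr)
  attr(one, "pollutant") <- "ufp"
  expect_error(fit_timetrend(one), ">= 2 shifts")

  far <- fit_ar(fr)
  ftt <- fit_timetrend(fr)
  ## without a true trend the shared time smooth stays near its null space
  ## and the covariate estimates agree within 1 SE
  for (tm in c("wind_speed", "temperature", "rh")) {
    e1 <- far$table[far$table$term == tm, ]
    e2 <- ftt$table[ftt$table$term == tm, ]
    se <- (e1$hi95 - e1$lo95) / (2 * 1.96)
    expect_lt(abs(e1$estimate - e2$estimate), se)
  }
})

test_that("a single-segment source term is equivalent to a direct distance smooth", {
  fr <- small_frame(seed = 36)
  seg <- discretize_road(road_source("pt", rbind(c(149.99, 400), c(150.01, 400)),
                                     counter_ids = "x"), 10)
  expect_equal(nrow(seg$segments), 1)
  seg$segments$e <- 1
  lam <- c(2, 5)
  fd <- fit_discretized(fr, list(wb = seg), k_g = 8, sp = lam,
                        use_ar = FALSE, traffic_weighted = FALSE)

  ## independent construction of the same term through mgcv
  d <- sqrt((fr$easting - seg$segments$mid_x)^2 +
            (fr$northing - seg$segments$mid_y)^2)
  u <- sqrt(d)
  qs <- as.numeric(stats::quantile(u, probs = seq(0, 1, length.out = 8)))
  smr <- mgcv::smoothCon(mgcv::s(x, bs = "cr", k = 8),
                         data = data.frame(x = u), absorb.cons = FALSE,
                         knots = list(x = qs))[[1]]
  H <- qr.Q(qr(matrix(1, 8, 1)), complete = TRUE)[, -1, drop = FALSE]
  term <- structure(list(name = "g", X = smr$X %*% H,
                         S = t(H) %*% smr$S[[1]] %*% H, null_dim = 1,
                         evalmat = NULL), class = "smooth_term")
  sms <- list(term,
              build_spatial_basis(cbind(fr$easting, fr$northing), k = 30))
  des <- mobilegam:::assemble_design(fr, "additive", roads = character(0),
                                     include_spatial = FALSE)
  pf <- fit_penalized(fr$y, des$X_par, sms, sp = lam)
  expect_lt(max(abs(fd$fit$beta - pf$beta)), 1e-6)
})

test_that("doubling segment weights halves g without changing unpenalized fits", {
  fr <- small_frame(seed = 37)
  segs <- list(bqe = discretize_road(road_source("B", rbind(c(150, 0), c(150, 800)),
                                                 counter_ids = "b"), 50))
  f1 <- fit_discretized(fr, segs, k_g = 6, sp = c(0, 1), use_ar = FALSE)
  segs2 <- segs
  segs2$bqe$segments$e <- 2 * segs2$bqe$segments$e
  f2 <- fit_discretized(fr, segs2, k_g = 6, sp = c(0, 1), use_ar = FALSE)
  expect_lt(max(abs(f1$fit$fitted - f2$fit$fitted)), 1e-6)
  idx <- f1$fit$blocks$g
  expect_lt(max(abs(2 * f2$fit$beta[idx] - f1$fit$beta[idx])), 1e-6)
})

test_that("zero segment weights drop the pooled term with a warning", {
  fr <- small_frame(seed = 38)
  segs <- list(bqe = discretize_road(road_source("B", rbind(c(150, 0), c(150, 800)),
                                                 counter_ids = "b"), 100))
  segs$bqe$segments$e <- 0
  expect_warning(fd <- fit_discretized(fr, segs, use_ar = FALSE,
                                       traffic_weighted = FALSE),
                 "zero")
  expect_null(fd$fit$blocks$g)
})

test_that("day dummies drop automatically for a single sampling day", {
  fr <- small_frame(seed = 39)
  sub <- fr[fr$day_id == levels(fr$day_id)[1], ]
  class(sub) <- class(fr)
  attr(sub, "pollutant") <- "ufp"
  sub$day_id <- droplevels(sub$day_id)
  expect_message(fa <- fit_additive(sub), "day dummies dropped")
  expect_false(any(grepl("^day_", fa$table$term)))
})

test_that("sensitivity refits honour strata, labels and minimum sizes", {
  cmp <- generate_campaign(preset("sector_decay", n_shifts = 6,
                                  minutes_per_shift = 70, n_backpacks = 2,
                                  seed = 40))
  fr <- campaign_frame(cmp)
  sens <- suppressWarnings(
    sensitivity_suite(fr, which = c("wind", "single_road", "traffic_class")))
  expect_true(all(c("WB_only", "BQE_only", "traffic_class") %in%
                  names(sens$fits)))
  expect_true(is.data.frame(sens$comparison))
  ## vehicle-class covariates barely move R^2
  base <- fit_ar(fr)
  expect_lt(abs(sens$fits$traffic_class$r2 - base$r2), 0.02)
  ## single-roadway models retain only their own curve
  expect_identical(names(sens$fits$WB_only$curves), "WB")
  ## a stratum below the row floor is skipped with a warning
  w <- capture_warnings(sensitivity_suite(fr[1:250, ], which = "wind",
                                          min_rows = 200))
  expect_true(any(grepl("skipped", w)))
})
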