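## The four estimators: the initial additive model, its AR(p)-error refit
## with empirically selected order, the long-term time-trend model with
## per-shift smooths, and the discretized line-source model, plus
## distance-curve prediction and the stratified sensitivity refits.

## ---- design assembly -----------------------------------------------------

## Build the parametric design, smooth list and distance-term registry shared
## by all model kinds.
assemble_design <- function(frame, model = c("additive", "timetrend"),
                            roads = c("wb", "bqe"), k_dist = 10,
                            k_spatial = 30, k_time = 10,
                            traffic_terms = c("total", "class", "speed"),
                            smooth_covariates = FALSE,
                            include_spatial = TRUE) {
  model <- match.arg(model)
  traffic_terms <- match.arg(traffic_terms)
  n <- nrow(frame)

  tr_cols <- switch(traffic_terms,
    total = c("traffic_wb", "traffic_bqe"),
    class = c("traffic_wb_car", "traffic_wb_truckbus",
              "traffic_bqe_car", "traffic_bqe_truckbus"),
    speed = c("traffic_wb_slow", "traffic_wb_med", "traffic_wb_fast",
              "traffic_bqe_slow", "traffic_bqe_med", "traffic_bqe_fast"))
  miss <- setdiff(tr_cols, names(frame))
  if (length(miss))
    stop("frame lacks traffic columns: ", paste(miss, collapse = ", "))

  met_cols <- c("wind_speed", "temperature", "rh")
  Xp <- cbind(`(Intercept)` = rep(1, n),
              as.matrix(frame[, tr_cols, drop = FALSE]))

  smooths <- list()
  if (smooth_covariates) {
    for (cc in met_cols)
      smooths[[length(smooths) + 1]] <-
        build_univariate_basis(frame[[cc]], k = 5, name = paste0("f_", cc))
  } else {
    Xp <- cbind(Xp, as.matrix(frame[, met_cols]))
  }

  if (model == "additive") {
    day <- droplevels(factor(frame$day_id))
    if (nlevels(day) > 1) {
      D <- stats::model.matrix(~day, data.frame(day = day))[, -1, drop = FALSE]
      colnames(D) <- paste0("day_", levels(day)[-1])
      Xp <- cbind(Xp, D)
    } else {
      message("single sampling day: day dummies dropped")
    }
  } else {
    sh <- droplevels(factor(frame$shift_id))
    if (nlevels(sh) < 2) stop("time-trend model needs >= 2 shifts")
    S <- stats::model.matrix(~sh, data.frame(sh = sh))[, -1, drop = FALSE]
    colnames(S) <- paste0("shift_", levels(sh)[-1])
    Xp <- cbind(Xp, S)
  }

  ## distance smooths live on the sqrt-distance scale: near-road decay packs
  ## its curvature into the first tens of metres
  dist_terms <- list()
  if ("wb" %in% roads) {
    smWB <- build_univariate_basis(frame$d_wb, k = k_dist, name = "f_WB",
                                   transform = "sqrt")
    smooths[[length(smooths) + 1]] <- smWB
    dist_terms[["WB"]] <- list(term = "f_WB", obs = frame$d_wb,
                               evalmat = smWB$evalmat)
  }
  if ("bqe" %in% roads) {
    smBQE <- build_univariate_basis(frame$d_bqe, k = k_dist, name = "f_BQE",
                                    transform = "sqrt")
    smooths[[length(smooths) + 1]] <- smBQE
    dist_terms[["BQE"]] <- list(term = "f_BQE", obs = frame$d_bqe,
                                evalmat = smBQE$evalmat)
  }
  if (include_spatial)
    smooths[[length(smooths) + 1]] <-
      build_spatial_basis(cbind(frame$easting, frame$northing), k = k_spatial)

  if (model == "timetrend") {
    ft <- build_timesmooth(frame, k_time = k_time)
    if (!is.null(ft$smooth)) smooths[[length(smooths) + 1]] <- ft$smooth
    if (!is.null(ft$linear)) Xp <- cbind(Xp, ft$linear)
  }

  list(X_par = Xp, smooths = smooths, dist_terms = dist_terms)
}

## One centred cubic-spline time smooth per shift, assembled as a single
## block-diagonal term with one shared smoothing parameter (factor-smooth
## style). Shifts too short for a smooth get an unpenalized centred linear
## column instead.
build_timesmooth <- function(frame, k_time = 10) {
  sh <- as.character(frame$shift_id)
  shifts <- unique(sh)
  n <- nrow(frame)
  Xblocks <- list(); Sblocks <- list(); rowsl <- list()
  lincols <- NULL
  for (s in shifts) {
    rows <- which(sh == s)
    ts <- frame$t_shift[rows]
    if (length(unique(ts)) < k_time + 2) {
      lc <- numeric(n)
      lc[rows] <- ts - mean(ts)
      lincols <- cbind(lincols, lc)
      colnames(lincols)[ncol(lincols)] <- paste0("t_lin_", s)
      message("shift ", s, ": too short for a time smooth; linear trend used")
      next
    }
    b <- build_univariate_basis(ts, k = k_time, name = paste0("f_t_", s))
    Xblocks[[s]] <- b$X; Sblocks[[s]] <- b$S; rowsl[[s]] <- rows
  }
  smooth <- NULL
  if (length(Xblocks)) {
    p_each <- vapply(Xblocks, ncol, 1L)
    ptot <- sum(p_each)
    X <- matrix(0, n, ptot); S <- matrix(0, ptot, ptot)
    pos <- 0
    for (s in names(Xblocks)) {
      cols <- pos + seq_len(p_each[[s]])
      X[rowsl[[s]], cols] <- Xblocks[[s]]
      S[cols, cols] <- Sblocks[[s]]
      pos <- pos + p_each[[s]]
    }
    smooth <- structure(list(name = "f_t", X = X, S = S,
                             null_dim = length(Xblocks), evalmat = NULL),
                        class = "smooth_term")
  }
  list(smooth = smooth, linear = lincols)
}

## ---- FitResult container -------------------------------------------------

new_mg_fit <- function(kind, pollutant, pf, dist_terms, ar = NULL) {
  tab <- parametric_table(pf)
  for (nm in setdiff(names(pf$blocks), "parametric")) {
    tab <- rbind(tab, data.frame(term = nm, estimate = NA_real_,
                                 lo95 = NA_real_, hi95 = NA_real_,
                                 p = smooth_pvalue(pf, nm)))
  }
  x <- structure(list(model_kind = kind, pollutant = pollutant, fit = pf,
                      ar = ar, dist_terms = dist_terms, table = tab,
                      r2 = pf$r2, curves = list()),
                 class = "mg_fit")
  for (rid in names(dist_terms))
    x$curves[[rid]] <- predict_distance_curve(x, rid)
  x
}

#' @export
print.mg_fit <- function(x, ...) {
  cat(sprintf("%s model for %s: n = %d, R2 = %.3f\n", x$model_kind,
              x$pollutant, x$fit$n, x$r2))
  if (!is.null(x$ar) && x$ar$order > 0)
    cat(sprintf("  AR(%d) errors, phi = %s\n", x$ar$order,
                paste(sprintf("%.3f", x$ar$phi), collapse = ", ")))
  for (rid in names(x$curves))
    cat(sprintf("  %s: %.1f%% decrease within 100 m\n", rid,
                attr(x$curves[[rid]], "pct_decrease_100m")))
  invisible(x)
}

## ---- the four estimators -------------------------------------------------

#' Initial additive model (independent errors)
#'
#' Fits `y ~ X beta + f_WB(d_WB) + f_BQE(d_BQE) + f_s(s)` with independent
#' errors, where `X` holds the traffic counts per roadway, wind speed,
#' temperature, RH and sampling-day dummies, all entered linearly.
#'
#' @param frame A `model_frame` from [build_model_frame()].
#' @param k_dist,k_spatial Basis dimensions for the distance and spatial
#'   smooths (defaults 10 and 30).
#' @param roads Which distance smooths to include (`"wb"`, `"bqe"`).
#' @param method Smoothing-parameter criterion, `"REML"` (default) or
#'   `"GCV"`.
#' @param traffic_terms `"total"` (default), `"class"` (cars vs trucks and
#'   buses) or `"speed"` (slow/medium/fast) traffic covariates.
#' @param smooth_covariates Enter wind speed, temperature and RH as smooths
#'   instead of linear terms.
#' @return An object of class `mg_fit` with elements `fit` (the
#'   [fit_penalized()] result), `table` (estimate / 95% CI / p per
#'   covariate, smooth terms p-only), `curves` (per-road
#'   [predict_distance_curve()] results) and `r2`.
#' @export
fit_additive <- function(frame, k_dist = 10, k_spatial = 30,
                         roads = c("wb", "bqe"), method = "REML",
                         traffic_terms = "total", smooth_covariates = FALSE) {
  des <- assemble_design(frame, "additive", roads = roads, k_dist = k_dist,
                         k_spatial = k_spatial, traffic_terms = traffic_terms,
                         smooth_covariates = smooth_covariates)
  pf <- fit_penalized(frame$y, des$X_par, des$smooths, method = method)
  new_mg_fit("additive", attr(frame, "pollutant") %||% "pollutant", pf,
             des$dist_terms)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Empirical AR order selection on per-shift residual series
#'
#' Autocovariances are computed within each residual series (one backpack's
#' route within one shift; correlation never crosses series boundaries),
#' pooled across series with length weighting, and the Levinson-Durbin
#' recursion yields the Yule-Walker AR(p) fit for every order `0..p_max`.
#' The order minimising the information criterion computed from the pooled
#' innovation variance is returned with its coefficients. BIC is the
#' default: order identification needs a consistent criterion (AIC retains a
#' non-vanishing overfitting probability at any sample size).
#'
#' @param residuals Numeric residual vector (time order within series).
#' @param shifts Series id per residual (shift, or shift x backpack).
#' @param p_max Maximum order to consider (default 5).
#' @param criterion `"bic"` (default) or `"aic"`.
#' @return An [ar_structure()] (order possibly 0).
#' @export
select_ar_order <- function(residuals, shifts, p_max = 5,
                            criterion = c("bic", "aic")) {
  criterion <- match.arg(criterion)
  byshift <- split(residuals, factor(shifts, levels = unique(shifts)))
  if (all(lengths(byshift) < p_max + 6))
    stop("all shift series are shorter than p_max + 6; reduce p_max")
  r <- residuals - mean(residuals)
  N <- length(r)
  mu <- mean(residuals)
  gamma <- numeric(p_max + 1)
  for (lag in 0:p_max) {
    acc <- 0
    for (sg in byshift) {
      sg <- sg - mu
      ns <- length(sg)
      if (ns > lag) acc <- acc + sum(sg[1:(ns - lag)] * sg[(1 + lag):ns])
    }
    gamma[lag + 1] <- acc / N
  }
  dl <- durbin_levinson(gamma)
  pen <- if (criterion == "aic") 2 else log(N)
  crit <- N * log(dl$v) + pen * (0:p_max)
  p_best <- which.min(crit) - 1L
  phi <- if (p_best == 0) numeric(0) else dl$phi[[p_best]]
  ar_structure(p_best, phi, sigma2 = dl$v[p_best + 1])
}

#' AR-error model (two-stage penalized GLS)
#'
#' Stage 1 fits the initial additive model; stage 2 selects the AR order and
#' coefficients from its per-shift residuals ([select_ar_order()]); stage 3
#' refits the identical mean structure by penalized GLS with the AR
#' parameters held fixed (within-shift whitening).
#'
#' @inheritParams fit_additive
#' @param p_max Maximum AR order considered.
#' @param ar Optionally, a fixed [ar_structure()] to skip the selection.
#' @return An `mg_fit` (model_kind `"ar"`) whose `ar` element records the
#'   selected structure.
#' @export
fit_ar <- function(frame, k_dist = 10, k_spatial = 30, roads = c("wb", "bqe"),
                   method = "REML", p_max = 5, traffic_terms = "total",
                   smooth_covariates = FALSE, ar = NULL) {
  des <- assemble_design(frame, "additive", roads = roads, k_dist = k_dist,
                         k_spatial = k_spatial, traffic_terms = traffic_terms,
                         smooth_covariates = smooth_covariates)
  pf0 <- fit_penalized(frame$y, des$X_par, des$smooths, method = method)
  if (is.null(ar))
    ar <- select_ar_order(pf0$residuals, ar_groups(frame), p_max = p_max)
  pf <- if (ar$order == 0) pf0 else
    fit_penalized(frame$y, des$X_par, des$smooths, ar = ar,
                  groups = ar_groups(frame), method = method)
  new_mg_fit("ar", attr(frame, "pollutant") %||% "pollutant", pf,
             des$dist_terms, ar = ar)
}

#' Long-term time-trend model
#'
#' The additive mean structure plus a main effect of sampling shift (in
#' place of the day dummies, since shift nests day) and one centred smooth
#' function of time within each shift, with AR errors handled by the same
#' two-stage procedure as [fit_ar()].
#'
#' @inheritParams fit_ar
#' @param k_time Basis dimension of each per-shift time smooth (default 10);
#'   shifts shorter than `k_time + 2` minutes fall back to a linear trend.
#' @return An `mg_fit` (model_kind `"timetrend"`).
#' @export
fit_timetrend <- function(frame, k_dist = 10, k_spatial = 30, k_time = 10,
                          roads = c("wb", "bqe"), method = "REML", p_max = 5,
                          traffic_terms = "total", ar = NULL) {
  des <- assemble_design(frame, "timetrend", roads = roads, k_dist = k_dist,
                         k_spatial = k_spatial, k_time = k_time,
                         traffic_terms = traffic_terms)
  pf0 <- fit_penalized(frame$y, des$X_par, des$smooths, method = method)
  if (is.null(ar))
    ar <- select_ar_order(pf0$residuals, ar_groups(frame), p_max = p_max)
  pf <- if (ar$order == 0) pf0 else
    fit_penalized(frame$y, des$X_par, des$smooths, ar = ar,
                  groups = ar_groups(frame), method = method)
  new_mg_fit("timetrend", attr(frame, "pollutant") %||% "pollutant", pf,
             des$dist_terms, ar = ar)
}

#' Discretized line-source model
#'
#' Replaces the per-road distance smooths with a single pooled source term:
#' both roads are cut into 10-m segments, each treated as an individual
#' source with traffic weight `e_j`, and for each basis function `B_k` of a
#' distance basis `g` the design column is `sum_j e_j B_k(d_ij)` over all
#' segments of both roads, where `d_ij` is the (height-corrected) distance
#' from observation `i` to segment `j`. The constant direction of the basis
#' is removed so the pooled term is identifiable next to the intercept and
#' traffic covariates; `g` is therefore reported only up to a level, as a
#' recentred curve.
#'
#' @inheritParams fit_ar
#' @param segmented Named list of [discretize_road()] results (names are
#'   road roles `"wb"`, `"bqe"`). Each segment's weight per minute is its
#'   `e` column (length fraction by default) times the road's per-minute
#'   traffic count.
#' @param k_g Dimension of the pooled distance basis (default 10).
#' @param use_ar Apply the two-stage AR refit (default TRUE).
#' @param sp Optional fixed smoothing parameters (pooled term then spatial).
#' @param traffic_weighted Multiply each segment weight by the road's
#'   per-minute traffic count (default TRUE); `FALSE` uses the static
#'   segment weights only.
#' @return An `mg_fit` (model_kind `"discretized"`) with a single curve
#'   named `"pooled"`: the recentred `g(d)` estimate.
#' @export
fit_discretized <- function(frame, segmented, k_g = 10, k_spatial = 30,
                            method = "REML", p_max = 5, use_ar = TRUE,
                            sp = NULL, traffic_weighted = TRUE) {
  n <- nrow(frame)
  Dl <- list(); El <- list()
  for (role in names(segmented)) {
    seg <- segmented[[role]]$segments
    tr <- if (traffic_weighted) frame[[paste0("traffic_", role)]] else
      rep(1, n)
    if (is.null(tr)) stop("frame lacks traffic column for road '", role, "'")
    dx <- outer(frame$easting, seg$mid_x, "-")
    dy <- outer(frame$northing, seg$mid_y, "-")
    G <- sqrt(dx^2 + dy^2)
    D <- sqrt(sweep(G^2, 2, seg$height^2, "+"))
    Dl[[role]] <- D
    El[[role]] <- outer(tr, seg$e)  # e_j(i) = traffic_i * segment weight
  }
  D <- do.call(cbind, Dl)
  E <- do.call(cbind, El)
  if (all(E == 0)) {
    warning("all segment weights are zero; pooled source term dropped")
    E <- NULL
  }

  ## raw (uncentred) cubic basis over the pooled distances (sqrt scale, as
  ## for the direct distance smooths); remove the constant direction
  ## (the cardinal basis sums to one) via an orthonormal complement
  uval <- sqrt(as.numeric(D))
  qs <- stats::quantile(uval, probs = seq(0, 1, length.out = k_g))
  sm_raw <- mgcv::smoothCon(mgcv::s(x, bs = "cr", k = k_g),
                            data = data.frame(x = uval),
                            absorb.cons = FALSE,
                            knots = list(x = as.numeric(qs)))[[1]]
  H <- qr.Q(qr(matrix(1, k_g, 1)), complete = TRUE)[, -1, drop = FALSE]
  Sg <- t(H) %*% sm_raw$S[[1]] %*% H
  evalg <- function(v)
    mgcv::PredictMat(sm_raw, data.frame(x = sqrt(pmax(v, 0)))) %*% H

  smooths <- list()
  dist_terms <- list()
  if (!is.null(E)) {
    Z <- matrix(0, n, k_g)
    ## sum_j e_ij B_k(d_ij), assembled column-block-wise to bound memory
    Braw <- mgcv::PredictMat(sm_raw, data.frame(x = uval))
    for (k in seq_len(k_g)) {
      Bk <- matrix(Braw[, k], n, ncol(D))
      Z[, k] <- rowSums(E * Bk)
    }
    Zc <- Z %*% H
    smooths[[1]] <- structure(list(name = "g", X = Zc, S = Sg,
                                   null_dim = 1, evalmat = evalg),
                              class = "smooth_term")
    dist_terms[["pooled"]] <- list(term = "g", obs = as.numeric(D),
                                   evalmat = evalg)
  }
  smooths[[length(smooths) + 1]] <-
    build_spatial_basis(cbind(frame$easting, frame$northing), k = k_spatial)

  des <- assemble_design(frame, "additive", roads = character(0),
                         k_spatial = k_spatial, include_spatial = FALSE)
  Xp <- des$X_par
  smooths_all <- smooths

  pf0 <- fit_penalized(frame$y, Xp, smooths_all, method = method, sp = sp)
  ar <- NULL
  pf <- pf0
  if (use_ar) {
    ar <- select_ar_order(pf0$residuals, ar_groups(frame), p_max = p_max)
    if (ar$order > 0)
      pf <- fit_penalized(frame$y, Xp, smooths_all, ar = ar,
                          groups = ar_groups(frame), method = method, sp = sp)
  }
  new_mg_fit("discretized", attr(frame, "pollutant") %||% "pollutant", pf,
             dist_terms, ar = ar)
}

## `assemble_design` adds its own spatial smooth and distance smooths; for the
## discretized model we only want its parametric block, so it is called with
## roads = character(0) and its spatial smooth discarded above.

#' Implied aggregate distance curve of a discretized-source fit
#'
#' Evaluates the total fitted source contribution
#' `F(p) = sum_j e_j g(d_pj)` of one road's segments at probe points `p`,
#' recentred at the first probe, with pointwise 95% CIs. This is the curve
#' comparable to a direct per-road distance smooth.
#'
#' @param x A discretized `mg_fit`.
#' @param segmented The [discretize_road()] result for the road of interest.
#' @param probe_points Two-column matrix of probe locations.
#' @param traffic Per-minute traffic count at which to evaluate the weights
#'   (e.g. the sample mean).
#' @return A `distance_curve`-style data frame (index = probe order).
#' @export
aggregate_source_curve <- function(x, segmented, probe_points, traffic = 1) {
  seg <- segmented$segments
  probe_points <- as.matrix(rbind(probe_points))
  G <- sqrt(outer(probe_points[, 1], seg$mid_x, "-")^2 +
            outer(probe_points[, 2], seg$mid_y, "-")^2)
  D <- sqrt(sweep(G^2, 2, seg$height^2, "+"))
  ev <- x$dist_terms[["pooled"]]$evalmat
  pf <- x$fit
  idx <- pf$blocks[["g"]]
  np <- nrow(probe_points)
  kk <- length(idx)
  Crow <- matrix(0, np, kk)
  for (i in seq_len(np)) {
    B <- ev(D[i, ])
    Crow[i, ] <- colSums((traffic * seg$e) * B)
  }
  Crow <- sweep(Crow, 2, Crow[1, ])
  eta <- as.numeric(Crow %*% pf$beta[idx])
  V <- pf$Vp[idx, idx, drop = FALSE]
  se <- sqrt(pmax(rowSums((Crow %*% V) * Crow), 0))
  data.frame(eta = eta, lo95 = eta - 1.96 * se, hi95 = eta + 1.96 * se)
}

## ---- distance curves -----------------------------------------------------

#' Adjusted distance-decay curve with pointwise 95% CI
#'
#' Evaluates the fitted distance smooth for one road on a distance grid,
#' recentres it so the first grid point (the minimum observed distance by
#' default) is zero, and propagates the coefficient covariance to pointwise
#' 95% intervals. The summary `pct_decrease_100m` is
#' `100 * (1 - exp(eta(100) - eta(d_min)))`, the adjusted percent decrease in
#' concentration between the road-edge reference and 100 m.
#'
#' @param x An `mg_fit`.
#' @param road_id Name of a curve in the fit (`"WB"`, `"BQE"`, or
#'   `"pooled"` for discretized fits).
#' @param grid Distance grid (metres, ascending). Default: minimum observed
#'   distance to `max_distance` in `step`-m increments, truncated (with a
#'   warning if explicitly requested) to the observed range.
#' @param max_distance,step Grid construction parameters (defaults 500 and 5).
#' @return A `distance_curve`: data frame `distance`, `eta`, `lo95`, `hi95`
#'   with attributes `road_id`, `pct_decrease_100m`, `ci_width_100m`.
#' @export
predict_distance_curve <- function(x, road_id = "WB", grid = NULL,
                                   max_distance = 500, step = 5) {
  info <- x$dist_terms[[road_id]]
  if (is.null(info)) stop("fit has no distance term for road '", road_id, "'")
  pf <- x$fit
  dmin <- min(info$obs); dmax <- max(info$obs)
  if (is.null(grid)) {
    grid <- seq(dmin, min(max_distance, dmax), by = step)
  } else {
    out <- grid < dmin | grid > dmax
    if (any(out)) {
      warning("grid truncated to the observed distance range [",
              round(dmin, 1), ", ", round(dmax, 1), "] m (no extrapolation)")
      grid <- grid[!out]
    }
  }
  if (length(grid) < 2) stop("distance grid has fewer than 2 usable points")
  B <- info$evalmat(grid)
  idx <- pf$blocks[[info$term]]
  C <- sweep(B, 2, B[1, ])
  eta <- as.numeric(C %*% pf$beta[idx])
  V <- pf$Vp[idx, idx, drop = FALSE]
  se <- sqrt(pmax(rowSums((C %*% V) * C), 0))
  lo <- eta - 1.96 * se; hi <- eta + 1.96 * se
  if (100 >= grid[1] && 100 <= grid[length(grid)]) {
    eta100 <- stats::approx(grid, eta, xout = 100)$y
    pct <- 100 * (1 - exp(eta100))
    wid <- stats::approx(grid, hi, xout = 100)$y -
      stats::approx(grid, lo, xout = 100)$y
  } else {
    pct <- NA_real_; wid <- NA_real_
  }
  structure(data.frame(distance = grid, eta = eta, lo95 = lo, hi95 = hi),
            road_id = road_id, pct_decrease_100m = pct, ci_width_100m = wid,
            class = c("distance_curve", "data.frame"))
}

#' @export
print.distance_curve <- function(x, ...) {
  cat(sprintf("distance_curve %s: %d grid points [%.1f, %.1f] m, %.1f%% decrease within 100 m\n",
              attr(x, "road_id"), nrow(x), x$distance[1],
              x$distance[nrow(x)], attr(x, "pct_decrease_100m")))
  invisible(x)
}

## ---- sensitivity suite ---------------------------------------------------

#' Stratified and alternative-covariate sensitivity refits
#'
#' Re-runs the AR model under the sensitivity configurations: upwind versus
#' downwind strata per road (single-roadway models, calm minutes excluded),
#' vehicle-class and vehicle-speed traffic covariates, high/low median
#' traffic splits (per-road counter), single-roadway models, smoothed
#' meteorology covariates, and an alternative weather stream.
#'
#' @param frame A `model_frame`.
#' @param which Character vector of analyses: any of `"wind"`,
#'   `"traffic_class"`, `"traffic_speed"`, `"high_low"`, `"single_road"`,
#'   `"smooth_covariates"`, `"alt_weather"`.
#' @param alt_weather Optional data frame `minute`, `wind_speed` replacing
#'   the wind-speed covariate for the `"alt_weather"` analysis.
#' @param min_rows Strata smaller than this are skipped with a warning
#'   (default 200).
#' @param ... Passed to [fit_ar()].
#' @return List with `fits` (named `mg_fit`s) and `comparison`, a data frame
#'   of per-analysis distance-term p-values, R^2 and percent decreases.
#' @export
sensitivity_suite <- function(frame, which = c("wind", "single_road"),
                              alt_weather = NULL, min_rows = 200, ...) {
  fits <- list()
  add_fit <- function(label, sub, ...) {
    if (nrow(sub) < min_rows) {
      warning("stratum '", label, "' has ", nrow(sub), " rows (< ", min_rows,
              "); skipped")
      return(invisible(NULL))
    }
    fits[[label]] <<- fit_ar(sub, ...)
  }
  roles <- c(WB = "wb", BQE = "bqe")
  if ("wind" %in% which) {
    for (rid in names(roles)) {
      sec <- frame[[paste0("sector_", roles[[rid]])]]
      for (s in c("upwind", "downwind"))
        add_fit(paste0(rid, "_", s), frame[sec == s, , drop = FALSE],
                roads = roles[[rid]], ...)
    }
  }
  if ("traffic_class" %in% which)
    fits[["traffic_class"]] <- fit_ar(frame, traffic_terms = "class", ...)
  if ("traffic_speed" %in% which)
    fits[["traffic_speed"]] <- fit_ar(frame, traffic_terms = "speed", ...)
  if ("high_low" %in% which) {
    for (rid in names(roles)) {
      hi <- median_split(frame, paste0("traffic_", roles[[rid]]))
      add_fit(paste0(rid, "_high"), frame[hi, , drop = FALSE],
              roads = roles[[rid]], ...)
      add_fit(paste0(rid, "_low"), frame[!hi, , drop = FALSE],
              roads = roles[[rid]], ...)
    }
  }
  if ("single_road" %in% which) {
    fits[["WB_only"]] <- fit_ar(frame, roads = "wb", ...)
    fits[["BQE_only"]] <- fit_ar(frame, roads = "bqe", ...)
  }
  if ("smooth_covariates" %in% which)
    fits[["smooth_covariates"]] <- fit_ar(frame, smooth_covariates = TRUE, ...)
  if ("alt_weather" %in% which) {
    if (is.null(alt_weather)) stop("'alt_weather' data frame required")
    sub <- frame
    m <- match(sub$minute, alt_weather$minute)
    sub$wind_speed <- alt_weather$wind_speed[m]
    sub <- sub[!is.na(sub$wind_speed), , drop = FALSE]
    fits[["alt_weather"]] <- fit_ar(sub, ...)
  }

  rows <- lapply(names(fits), function(lb) {
    f <- fits[[lb]]
    getp <- function(tm) {
      r <- f$table$p[f$table$term == tm]
      if (length(r)) r[1] else NA_real_
    }
    getpct <- function(rid) {
      if (is.null(f$curves[[rid]])) NA_real_
      else attr(f$curves[[rid]], "pct_decrease_100m")
    }
    data.frame(analysis = lb, n = f$fit$n, r2 = f$r2,
               p_f_WB = getp("f_WB"), p_f_BQE = getp("f_BQE"),
               pct100_WB = getpct("WB"), pct100_BQE = getpct("BQE"))
  })
  list(fits = fits, comparison = do.call(rbind, rows))
}
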