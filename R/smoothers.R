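## Penalized-spline machinery: bases + penalties (via mgcv::smoothCon),
## AR(p) innovations whitening, penalized (generalized) least squares with
## REML/GCV smoothing-parameter selection (via mgcv::gam with paraPen on the
## whitened design), and approximate Wald inference for smooth terms.

#' Cubic regression spline basis with roughness penalty
#'
#' Builds a centred cubic regression spline basis (knots at quantiles of the
#' observed values) with its second-derivative roughness penalty. The
#' sum-to-zero constraint over the observed values is absorbed into the
#' basis, so any fitted smooth averages to zero over the data. If the
#' covariate has fewer than 25 distinct values the dimension falls back to
#' `min(k, n_distinct - 2)`.
#'
#' @param values Numeric covariate sample.
#' @param k Basis dimension before the centring constraint (default 10).
#' @param name Term label (e.g. `"f_WB"`).
#' @param transform `"identity"` (default) builds the spline directly on the
#'   covariate; `"sqrt"` builds it on the square-root scale (used for
#'   distance-to-source smooths, where the decay concentrates its curvature
#'   near the road: on the root scale the knots and the roughness penalty
#'   give the near-source region its share of resolution). The term is
#'   still evaluated and reported on the original scale.
#' @return A `smooth_term`: list with `name`, design matrix `X` (n x (k-1)),
#'   penalty `S`, `null_dim` (penalty null-space dimension after centring),
#'   and `evalmat(newvalues)` returning the prediction matrix.
#' @export
build_univariate_basis <- function(values, k = 10, name = "f",
                                   transform = c("identity", "sqrt")) {
  transform <- match.arg(transform)
  values <- as.numeric(values)
  tf <- if (transform == "sqrt") function(v) sqrt(pmax(v, 0)) else identity
  tv <- tf(values)
  ndist <- length(unique(tv))
  if (ndist < 25) k <- min(k, ndist - 2)
  if (ndist < 4 || k < 3)
    stop("covariate '", name, "' has too few distinct values (", ndist,
         ") for a smooth; reduce k or drop the term")
  dat <- data.frame(x = tv)
  sm <- mgcv::smoothCon(mgcv::s(x, bs = "cr", k = k), data = dat,
                        absorb.cons = TRUE)[[1]]
  structure(list(name = name, X = sm$X, S = sm$S[[1]], sm = sm,
                 null_dim = ncol(sm$X) - sm$rank,
                 range = range(values), transform = transform,
                 evalmat = function(v) mgcv::PredictMat(sm, data.frame(x = tf(v)))),
            class = "smooth_term")
}

#' Low-rank thin-plate spatial basis
#'
#' Thin-plate regression spline over planar coordinates: an eigen-truncated
#' radial basis with the standard thin-plate penalty whose null space is the
#' affine surface (unpenalized). Mean-centred over the observed locations.
#'
#' @param coords Two-column matrix of planar coordinates (metres).
#' @param k Basis dimension (default 30); `k = 3` degenerates to the affine
#'   null space only.
#' @param max_knots Locations are subsampled to at most this many knots for
#'   the eigen decomposition (default 500).
#' @inheritParams build_univariate_basis
#' @return A `smooth_term`; `evalmat` takes a two-column coordinate matrix.
#' @export
build_spatial_basis <- function(coords, k = 30, name = "f_s", max_knots = 500) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 2) stop("'coords' must have two columns")
  ## reject an effectively one-dimensional point cloud
  ev <- eigen(stats::cov(coords), symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= 1e-10 * max(ev[1], 1))
    stop("spatial locations are collinear; a bivariate smooth is not identifiable")
  dat <- data.frame(x = coords[, 1], y = coords[, 2])
  sm <- mgcv::smoothCon(mgcv::s(x, y, bs = "tp", k = k),
                        data = dat, absorb.cons = TRUE,
                        knots = NULL)[[1]]
  structure(list(name = name, X = sm$X, S = sm$S[[1]], sm = sm,
                 null_dim = ncol(sm$X) - sm$rank,
                 evalmat = function(xy) {
                   xy <- as.matrix(rbind(xy))
                   mgcv::PredictMat(sm, data.frame(x = xy[, 1], y = xy[, 2]))
                 }),
            class = "smooth_term")
}

#' AR(p) error structure
#'
#' @param order Non-negative integer AR order.
#' @param phi Numeric vector of `order` autoregressive coefficients; the AR
#'   polynomial must be stationary.
#' @param sigma2 Innovation variance (> 0), default 1.
#' @return Object of class `ar_structure`.
#' @export
ar_structure <- function(order, phi = numeric(0), sigma2 = 1) {
  order <- as.integer(order)
  if (length(phi) != order) stop("length(phi) must equal 'order'")
  if (order > 0) {
    r <- polyroot(c(1, -phi))
    if (any(Mod(r) <= 1 + 1e-8)) stop("AR coefficients are not stationary")
  }
  if (sigma2 <= 0) stop("'sigma2' must be positive")
  structure(list(order = order, phi = as.numeric(phi), sigma2 = sigma2),
            class = "ar_structure")
}

## Levinson-Durbin recursion on autocovariances gamma_0..gamma_p.
## Returns the best linear predictor coefficients of each order m (phi[[m]])
## and the prediction error variances v[m + 1] (v[1] = gamma_0).
durbin_levinson <- function(gamma) {
  p <- length(gamma) - 1
  phi <- vector("list", p)
  v <- numeric(p + 1)
  v[1] <- gamma[1]
  phi_prev <- numeric(0)
  for (m in seq_len(p)) {
    if (m == 1) kap <- gamma[2] / gamma[1]
    else kap <- (gamma[m + 1] - sum(phi_prev * gamma[m:2])) / v[m]
    phi_m <- c(phi_prev - kap * rev(phi_prev), kap)
    v[m + 1] <- v[m] * (1 - kap^2)
    phi[[m]] <- phi_m
    phi_prev <- phi_m
  }
  list(phi = phi, v = v)
}

## Theoretical autocovariances (unit innovation variance) of an AR(phi)
## process, lags 0..lag_max.
ar_autocov <- function(phi, lag_max) {
  p <- length(phi)
  if (p == 0) return(c(1, rep(0, lag_max)))
  rho <- stats::ARMAacf(ar = phi, lag.max = max(lag_max, p))
  gamma0 <- 1 / (1 - sum(phi * rho[2:(p + 1)]))
  as.numeric(rho[1:(lag_max + 1)] * gamma0)
}

#' Whiten a vector or matrix by the AR(p) innovations filter within groups
#'
#' Applies the exact innovations transform of the stationary AR(p) process to
#' each group (shift) independently: rows beyond the AR order become
#' `x_t - sum(phi_k x_(t-k))`, and the first `p` rows of each group use the
#' Levinson-Durbin partial predictors scaled to the same (unit innovation)
#' variance. For `W` the implied transform and `V` the AR correlation-scale
#' covariance, `W V W' = I`.
#'
#' @param x Numeric vector or matrix (rows in time order within group).
#' @param ar An [ar_structure()].
#' @param groups Grouping vector (e.g. shift id); correlation never crosses
#'   group boundaries. Default: one group.
#' @return Whitened object of the same shape.
#' @export
ar_whiten <- function(x, ar, groups = NULL) {
  xm <- as.matrix(x)
  p <- ar$order
  if (p == 0) return(x)
  if (is.null(groups)) groups <- rep(1L, nrow(xm))
  if (length(groups) != nrow(xm)) stop("'groups' length mismatch")
  dl <- durbin_levinson(ar_autocov(ar$phi, p))
  out <- xm
  for (g in unique(groups)) {
    idx <- which(groups == g)
    n <- length(idx)
    xg <- xm[idx, , drop = FALSE]
    wg <- xg
    for (i in seq_len(min(p, n))) {
      if (i == 1) pred <- 0
      else pred <- crossprod(dl$phi[[i - 1]], xg[(i - 1):1, , drop = FALSE])
      wg[i, ] <- (xg[i, ] - pred) / sqrt(dl$v[i])
    }
    if (n > p) {
      rows <- (p + 1):n
      acc <- xg[rows, , drop = FALSE]
      for (k in seq_len(p))
        acc <- acc - ar$phi[k] * xg[rows - k, , drop = FALSE]
      wg[rows, ] <- acc
    }
    out[idx, ] <- wg
  }
  if (is.matrix(x)) out else drop(out)
}

#' Penalized (generalized) least squares with smooth terms
#'
#' Fits `y ~ X_par beta + sum_j f_j` by penalized least squares, selecting
#' the smoothing parameters by REML (default) or GCV. When an AR error
#' structure is supplied its parameters are held fixed: the response and the
#' whole design are whitened within each group by [ar_whiten()] and the same
#' penalized solve is applied to the whitened problem, so the result is the
#' penalized generalized-least-squares fit. Fit statistics (fitted values,
#' residuals, R^2) are reported on the original, unwhitened scale.
#'
#' @param y Response vector (finite).
#' @param X_par Parametric design matrix with column names (include the
#'   intercept column explicitly).
#' @param smooths List of `smooth_term`s (from [build_univariate_basis()],
#'   [build_spatial_basis()] or custom).
#' @param ar Optional [ar_structure()] with fixed parameters.
#' @param groups Grouping vector for the whitening (required when `ar` has
#'   positive order).
#' @param method `"REML"` (default) or `"GCV"`.
#' @param sp Optional fixed smoothing parameters (one per smooth; `NA`
#'   entries are estimated).
#' @return Object of class `penalized_fit`: coefficients `beta`, Bayesian
#'   covariance `Vp` (used for intervals), frequentist `Ve`, smoothing
#'   parameters `sp`, residual (innovation) variance `sigma2`, per-term
#'   effective degrees of freedom `edf`, block index map `blocks`, fitted
#'   values/`residuals`/`r2` on the original scale, and the smooth terms.
#' @export
fit_penalized <- function(y, X_par, smooths = list(), ar = NULL, groups = NULL,
                          method = c("REML", "GCV"), sp = NULL) {
  method <- match.arg(method)
  if (any(!is.finite(y))) stop("non-finite values in 'y'")
  X_par <- as.matrix(X_par)
  if (is.null(colnames(X_par)))
    colnames(X_par) <- paste0("b", seq_len(ncol(X_par)))
  n <- length(y)
  stopifnot(nrow(X_par) == n)
  nsm <- length(smooths)
  if (!is.null(sp) && length(sp) != nsm)
    stop("'sp' must have one entry per smooth")

  ## rank check on the assembled (unpenalized) design
  Xall <- do.call(cbind, c(list(X_par), lapply(smooths, `[[`, "X")))
  qrx <- qr(Xall)
  if (qrx$rank < ncol(Xall)) {
    bad <- qrx$pivot[(qrx$rank + 1):ncol(Xall)]
    lab <- ifelse(bad <= ncol(X_par), colnames(X_par)[pmin(bad, ncol(X_par))],
                  "smooth basis column")
    stop("design is rank deficient; offending columns: ",
         paste(unique(lab), collapse = ", "))
  }

  whiten <- !is.null(ar) && ar$order > 0
  if (whiten && is.null(groups))
    stop("'groups' is required for AR whitening")
  yw <- if (whiten) ar_whiten(y, ar, groups) else y
  Xpw <- if (whiten) ar_whiten(X_par, ar, groups) else X_par

  dat <- list(yw = yw, Xp = Xpw)
  pp <- list()
  rhs <- "Xp"
  for (j in seq_len(nsm)) {
    nm <- paste0("Xs", j)
    Xj <- smooths[[j]]$X
    dat[[nm]] <- if (whiten) ar_whiten(Xj, ar, groups) else Xj
    entry <- list(smooths[[j]]$S)
    if (!is.null(sp) && !is.na(sp[j])) entry$sp <- sp[j]
    pp[[nm]] <- entry
    rhs <- c(rhs, nm)
  }
  form <- stats::as.formula(paste("yw ~", paste(rhs, collapse = " + "), "- 1"))
  ## degenerate responses (no residual variance left for REML/GCV) and rare
  ## optimizer failures fall back to a direct penalized solve at unit
  ## smoothing parameters (exact in the zero-variance case)
  direct_solve <- function() {
    Xw <- do.call(cbind, lapply(rhs, function(nm) dat[[nm]]))
    P <- matrix(0, ncol(Xw), ncol(Xw))
    pos <- ncol(Xpw)
    for (j in seq_len(nsm)) {
      kj <- ncol(smooths[[j]]$X)
      lam <- if (!is.null(sp) && !is.na(sp[j])) sp[j] else 1
      P[pos + 1:kj, pos + 1:kj] <- lam * smooths[[j]]$S
      pos <- pos + kj
    }
    A <- crossprod(Xw) + P
    Ai <- solve(A)
    bhat <- Ai %*% crossprod(Xw, yw)
    edf_all <- diag(Ai %*% crossprod(Xw))
    rss <- sum((yw - Xw %*% bhat)^2)
    sig2 <- rss / max(1, length(yw) - sum(edf_all))
    list(coefficients = as.numeric(bhat), Vp = sig2 * Ai, Ve = sig2 * Ai,
         sp = numeric(0), sig2 = sig2, edf = edf_all)
  }
  run_gam <- function() {
    mgcv::gam(form, data = dat,
              paraPen = if (length(pp)) pp else NULL,
              method = if (method == "REML") "REML" else "GCV.Cp")
  }
  gm <- if (stats::sd(yw) < 1e-10) direct_solve() else
    tryCatch(run_gam(), error = function(e) direct_solve())

  beta <- as.numeric(stats::coef(gm))
  np <- ncol(X_par)
  blocks <- list()
  blocks[["parametric"]] <- seq_len(np)
  pos <- np
  for (j in seq_len(nsm)) {
    kj <- ncol(smooths[[j]]$X)
    blocks[[smooths[[j]]$name]] <- pos + seq_len(kj)
    pos <- pos + kj
  }
  names(beta) <- c(colnames(X_par),
                   unlist(lapply(smooths, function(s)
                     paste0(s$name, ".", seq_len(ncol(s$X))))))

  fitted_orig <- as.numeric(Xall %*% beta)
  resid_orig <- y - fitted_orig
  edf <- vapply(seq_len(nsm), function(j) sum(gm$edf[blocks[[smooths[[j]]$name]]]),
                numeric(1))
  names(edf) <- vapply(smooths, `[[`, "", "name")
  spout <- if (length(gm$sp)) gm$sp else numeric(0)
  if (!is.null(sp)) {  # re-insert fixed entries in term order
    full <- sp
    full[is.na(sp)] <- spout
    spout <- full
  }
  r2 <- if (stats::sd(fitted_orig) == 0 || stats::sd(y) == 0) 0 else
    as.numeric(stats::cor(fitted_orig, y)^2)

  structure(list(beta = beta, Vp = gm$Vp, Ve = gm$Ve, sp = spout,
                 sigma2 = gm$sig2, edf = edf, blocks = blocks,
                 fitted = fitted_orig, residuals = resid_orig, r2 = r2,
                 smooths = smooths, par_names = colnames(X_par),
                 ar = ar, method = method, n = n, gam = gm),
            class = "penalized_fit")
}

#' @export
print.penalized_fit <- function(x, ...) {
  cat(sprintf("penalized_fit: n = %d, %d parametric + %d smooth term(s), R2 = %.3f\n",
              x$n, length(x$par_names), length(x$smooths), x$r2))
  if (!is.null(x$ar) && x$ar$order > 0)
    cat(sprintf("  AR(%d) errors, phi = %s\n", x$ar$order,
                paste(sprintf("%.3f", x$ar$phi), collapse = ", ")))
  invisible(x)
}

#' Approximate Wald test for a smooth term
#'
#' Tests all coefficients of the named smooth against zero with the Wald
#' statistic `b' V^- b` (pseudo-inverse of the term's covariance block)
#' referred to a chi-square with the term's effective degrees of freedom.
#' This is an approximation: the reference distribution ignores
#' smoothing-parameter selection.
#'
#' @param fit A [fit_penalized()] result.
#' @param term Name of the smooth.
#' @return p-value in `[0, 1]`.
#' @export
smooth_pvalue <- function(fit, term) {
  idx <- fit$blocks[[term]]
  if (is.null(idx)) stop("no smooth term '", term, "' in fit")
  b <- fit$beta[idx]
  V <- fit$Vp[idx, idx, drop = FALSE]
  eg <- eigen((V + t(V)) / 2, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  if (!any(pos) || sum(b^2) == 0) return(1)
  Vinvb <- eg$vectors[, pos, drop = FALSE] %*%
    ((t(eg$vectors[, pos, drop = FALSE]) %*% b) / eg$values[pos])
  stat <- sum(b * Vinvb)
  df <- max(fit$edf[term], 1e-3)
  min(1, max(0, stats::pchisq(stat, df = df, lower.tail = FALSE)))
}

## Wald table for the parametric block (normal reference).
parametric_table <- function(fit) {
  idx <- fit$blocks[["parametric"]]
  se <- sqrt(pmax(diag(fit$Vp)[idx], 0))
  est <- fit$beta[idx]
  z <- ifelse(se > 0, est / se, 0)
  data.frame(term = fit$par_names, estimate = est,
             lo95 = est - 1.96 * se, hi95 = est + 1.96 * se,
             p = 2 * stats::pnorm(-abs(z)), row.names = NULL,
             stringsAsFactors = FALSE)
}
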