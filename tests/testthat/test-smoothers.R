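test_that("univariate basis: partition of unity, centring and linear null space", {
  set.seed(1)
  x <- runif(200)
  ## raw cardinal cubic basis sums to one before centring
  sm_raw <- mgcv::smoothCon(mgcv::s(x, bs = "cr", k = 10),
                            data = data.frame(x = x), absorb.cons = FALSE)[[1]]
  expect_true(all(abs(rowSums(sm_raw$X) - 1) < 1e-10))

  b <- build_univariate_basis(x, k = 10)
  ## centred: any coefficient vector gives a mean-zero smooth over the data
  set.seed(2)
  for (i in 1:5) {
    co <- rnorm(ncol(b$X))
    expect_lt(abs(mean(b$X %*% co)), 1e-8)
  }
  ## a linear function incurs (almost) zero roughness penalty
  cf <- qr.coef(qr(b$X), 2 + 3 * x - mean(2 + 3 * x))
  expect_lt(as.numeric(t(cf) %*% b$S %*% cf) / max(abs(cf)), 1e-6)
  ## penalty symmetric PSD
  expect_equal(b$S, t(b$S), tolerance = 1e-12)
  expect_true(min(eigen(b$S, symmetric = TRUE, only.values = TRUE)$values) > -1e-8)

  expect_error(build_univariate_basis(rep(1, 50), k = 10), "distinct")
  ## few distinct values: dimension falls back
  xd <- rep(seq(0, 1, length.out = 12), 5)
  bd <- build_univariate_basis(xd, k = 10)
  expect_lte(ncol(bd$X), 9)
})

test_that("spatial basis: centring, affine null space, collinear rejection", {
  set.seed(3)
  xy <- cbind(runif(300), runif(300))
  b <- build_spatial_basis(xy, k = 20)
  set.seed(4)
  for (i in 1:5) {
    co <- rnorm(ncol(b$X))
    expect_lt(abs(mean(b$X %*% co)), 1e-8)
  }
  ## an affine surface incurs zero penalty
  z <- 1 + 2 * xy[, 1] - 3 * xy[, 2]
  cf <- qr.coef(qr(b$X), z - mean(z))
  expect_lt(as.numeric(t(cf) %*% b$S %*% cf) / sum(cf^2), 1e-8)
  expect_equal(b$null_dim, 2)
  ## k = 3 degenerates to (essentially) the affine part: at most one
  ## penalized direction survives beyond the 2-dim affine null space
  b3 <- suppressWarnings(build_spatial_basis(xy, k = 3))
  expect_lte(ncol(b3$X) - b3$null_dim, 1)
  expect_lte(ncol(b3$X), 3)

  line <- cbind(seq(0, 1, length.out = 50), 2 * seq(0, 1, length.out = 50))
  expect_error(build_spatial_basis(line), "collinear")
})

test_that("AR whitening reproduces the innovations transform exactly", {
  for (phi in list(0.5, c(0.4, 0.3), c(0.2875, 0.1825, 0.2))) {
    p <- length(phi)
    ar <- ar_structure(p, phi)
    n <- 60
    V <- stats::toeplitz(mobilegam:::ar_autocov(phi, n - 1))
    W <- ar_whiten(diag(n), ar)
    expect_lt(max(abs(W %*% V %*% t(W) - diag(n))), 1e-10)
  }
  ## groups whiten independently
  ar <- ar_structure(1, 0.6)
  x <- rnorm(40)
  g <- rep(1:2, each = 20)
  w <- ar_whiten(x, ar, g)
  expect_equal(w[1:20], ar_whiten(x[1:20], ar))
  expect_equal(w[21:40], ar_whiten(x[21:40], ar))

  expect_error(ar_structure(1, 1.0), "stationary")
  expect_error(ar_structure(2, 0.5), "length")
})

test_that("unpenalized fit equals the least-squares oracle", {
  set.seed(8)
  n <- 120
  X <- cbind(`(Intercept)` = 1, a = rnorm(n), b = runif(n))
  sm <- build_univariate_basis(runif(n), k = 6, name = "f")
  y <- rnorm(n)
  pf <- fit_penalized(y, X, list(sm), sp = 0)
  bls <- qr.coef(qr(cbind(X, sm$X)), y)
  expect_lt(max(abs(pf$beta - as.numeric(bls))), 1e-8)
  expect_equal(pf$fitted, as.numeric(cbind(X, sm$X) %*% pf$beta))
})

test_that("whitened penalized GLS equals brute-force covariance-based GLS", {
  set.seed(9)
  for (phi in list(0.5, c(0.4, 0.2), c(0.3, 0.2, 0.15))) {
    p <- length(phi)
    ar <- ar_structure(p, phi)
    n <- 150
    grp <- rep(1:3, each = 50)
    x <- runif(n)
    X <- cbind(`(Intercept)` = 1, z = rnorm(n))
    sm <- build_univariate_basis(x, k = 8, name = "f")
    y <- 1 + 0.5 * X[, 2] + sin(2 * pi * x) +
      as.numeric(vapply(1:3, function(i) mobilegam:::sim_ar(50, p, phi, 0.3),
                        numeric(50)))
    lam <- 3.7
    pf <- fit_penalized(y, X, list(sm), ar = ar, groups = grp, sp = lam)
    V1 <- stats::toeplitz(mobilegam:::ar_autocov(phi, 49))
    V <- matrix(0, n, n)
    for (i in 1:3) V[(i - 1) * 50 + 1:50, (i - 1) * 50 + 1:50] <- V1
    Xall <- cbind(X, sm$X)
    S <- matrix(0, ncol(Xall), ncol(Xall))
    S[3:ncol(Xall), 3:ncol(Xall)] <- lam * sm$S
    Vi <- solve(V)
    bb <- solve(t(Xall) %*% Vi %*% Xall + S, t(Xall) %*% Vi %*% y)
    expect_lt(max(abs(pf$beta - as.numeric(bb))), 1e-6)
  }
})

test_that("AR(1) with phi = 0 reproduces the independent-errors fit", {
  set.seed(10)
  n <- 100
  X <- cbind(`(Intercept)` = 1, z = rnorm(n))
  sm <- build_univariate_basis(runif(n), k = 6, name = "f")
  y <- rnorm(n)
  a <- fit_penalized(y, X, list(sm), sp = 1)
  b <- fit_penalized(y, X, list(sm), ar = ar_structure(1, 0),
                     groups = rep(1, n), sp = 1)
  expect_lt(max(abs(a$beta - b$beta)), 1e-10)
})

test_that("infinite penalty collapses smooths to their null space", {
  set.seed(12)
  n <- 300
  x <- runif(n)
  y <- sin(2 * pi * x) + rnorm(n, 0, 0.2)
  sm <- build_univariate_basis(x, k = 10, name = "f")
  pf <- fit_penalized(y, cbind(`(Intercept)` = rep(1, n)), list(sm), sp = 1e9)
  g <- seq(0.05, 0.95, length.out = 60)
  eta <- sm$evalmat(g) %*% pf$beta[pf$blocks$f]
  ## the surviving component is linear in x
  expect_lt(max(abs(stats::lm(eta ~ g)$residuals)), 1e-4)
})

test_that("effective degrees of freedom shrink monotonically in lambda", {
  set.seed(13)
  n <- 250
  x <- runif(n)
  y <- sin(2 * pi * x) + rnorm(n, 0, 0.3)
  sm <- build_univariate_basis(x, k = 10, name = "f")
  edfs <- vapply(10^seq(-4, 4, by = 1), function(l) {
    fit_penalized(y, cbind(`(Intercept)` = rep(1, n)), list(sm), sp = l)$edf["f"]
  }, numeric(1))
  expect_true(all(diff(edfs) < 1e-6))
  expect_gt(edfs[1], 7)          # near-unpenalized uses most of the basis
  expect_lt(edfs[length(edfs)], 2)  # collapses towards the 1-dim linear null space
})

test_that("REML lambda is competitive with the best fixed lambda", {
  set.seed(14)
  n <- 400
  x <- runif(n)
  f0 <- sin(2 * pi * x)
  y <- f0 + rnorm(n, 0, 0.4)
  sm <- build_univariate_basis(x, k = 12, name = "f")
  g <- seq(0.02, 0.98, length.out = 100)
  B <- sm$evalmat(g)
  truth <- sin(2 * pi * g) - mean(sin(2 * pi * x))
  ise <- function(pf) {
    eta <- pf$beta[1] + as.numeric(B %*% pf$beta[pf$blocks$f])
    mean((eta - (truth + mean(f0)))^2)
  }
  Xint <- cbind(`(Intercept)` = rep(1, n))
  ise_reml <- ise(fit_penalized(y, Xint, list(sm)))
  ise_grid <- vapply(10^seq(-5, 3, by = 0.5), function(l)
    ise(fit_penalized(y, Xint, list(sm), sp = l)), numeric(1))
  expect_lt(ise_reml, 2 * min(ise_grid))
})

test_that("saturated unpenalized fits dominate penalized fits in R^2", {
  set.seed(15)
  n <- 200
  x <- runif(n)
  y <- sin(2 * pi * x) + rnorm(n, 0, 0.5)
  sm <- build_univariate_basis(x, k = 10, name = "f")
  Xint <- cbind(`(Intercept)` = rep(1, n))
  r2_sat <- fit_penalized(y, Xint, list(sm), sp = 0)$r2
  for (l in c(0.01, 1, 100)) {
    expect_gte(r2_sat + 1e-10, fit_penalized(y, Xint, list(sm), sp = l)$r2)
  }
})

test_that("smooth Wald p-values behave at the null and under strong signal", {
  set.seed(16)
  n <- 2000
  x <- runif(n)
  sm <- build_univariate_basis(x, k = 10, name = "f")
  Xint <- cbind(`(Intercept)` = rep(1, n))
  ## strong decrement signal
  y <- 0.5 * exp(-4 * x) + rnorm(n, 0, 0.3)
  pf <- fit_penalized(y, Xint, list(sm))
  p_strong <- smooth_pvalue(pf, "f")
  expect_lt(p_strong, 0.001)
  ## permutation null on the same data: the observed Wald statistic should
  ## dominate statistics from fits with x decoupled from y
  stat_of <- function(pfit) {
    idx <- pfit$blocks$f
    b <- pfit$beta[idx]
    as.numeric(t(b) %*% solve(pfit$Vp[idx, idx] +
                                diag(1e-12, length(idx)), b))
  }
  obs_stat <- stat_of(pf)
  perm <- vapply(1:19, function(i) {
    xp <- sample(x)
    smp <- build_univariate_basis(xp, k = 10, name = "f")
    stat_of(fit_penalized(y, Xint, list(smp)))
  }, numeric(1))
  expect_true(obs_stat > max(perm))

  ## null: coefficients forced to zero give p = 1; p always in [0, 1]
  pf0 <- pf
  pf0$beta[pf0$blocks$f] <- 0
  expect_equal(smooth_pvalue(pf0, "f"), 1)
  for (i in 1:5) {
    yy <- rnorm(500)
    smn <- build_univariate_basis(runif(500), k = 8, name = "f")
    pn <- smooth_pvalue(fit_penalized(yy, cbind(`(Intercept)` = rep(1, 500)),
                                      list(smn)), "f")
    expect_gte(pn, 0)
    expect_lte(pn, 1)
  }
})

test_that("rank-deficient designs fail loudly with column names", {
  set.seed(17)
  n <- 80
  X <- cbind(`(Intercept)` = 1, a = rnorm(n))
  X <- cbind(X, dup = X[, "a"])
  expect_error(fit_penalized(rnorm(n), X), "rank deficient")
  expect_error(fit_penalized(c(NA, rnorm(n - 1)), X[, 1:2]), "non-finite")
})
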