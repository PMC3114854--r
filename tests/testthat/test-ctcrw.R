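test_that("exact discretization matches quadrature and limits", {
  p <- ctcrw_params(1, 1)
  m0 <- ctcrw_matrices(p, 0)
  expect_equal(m0$Phi, diag(2))
  expect_equal(m0$Q, matrix(0, 2, 2))
  expect_error(ctcrw_matrices(p, -1), ">= 0")

  # quadrature oracle: Q = int_0^dt g(s) g(s)' ds with g the impulse response
  dt <- 1
  m <- ctcrw_matrices(p, dt)
  g <- function(s, i) {
    e <- exp(-p$beta * (dt - s))
    c((1 - e) / p$beta, e)[i] * p$sigma
  }
  for (i in 1:2) for (j in i:2) {
    q <- integrate(Vectorize(function(s) g(s, i) * g(s, j)), 0, dt,
                   rel.tol = 1e-12)$value
    expect_lt(abs(q - m$Q[i, j]), 1e-8)
  }

  # stationary velocity variance sigma^2 / (2 beta)
  p2 <- ctcrw_params(0.7, 3)
  mInf <- ctcrw_matrices(p2, 1000)
  expect_equal(mInf$Q[2, 2], 3^2 / (2 * 0.7), tolerance = 1e-9)
})

test_that("filter log-likelihood equals the dense joint-Gaussian density", {
  set.seed(21)
  err <- error_model()
  for (r in 1:30) {
    n <- sample(2:10, 1)
    t <- sort(runif(n, 0, 30))
    cls <- sample(c("3", "2", "1", "0", "A", "B", "GL"), n, replace = TRUE)
    beta <- exp(runif(1, log(0.1), log(3)))
    sigma <- exp(runif(1, log(5), log(60)))
    xy <- simulate_ctcrw(t, ctcrw_params(beta, sigma))
    sds <- obs_error_sd(err, cls)
    x <- xy$x + rnorm(n, 0, sds$sd_lon_km)
    y <- xy$y + rnorm(n, 0, sds$sd_lat_km)
    obs <- obs_from_planar(t, x, y, cls)
    kf <- kalman_filter(obs, ctcrw_params(beta, sigma), err)
    pr <- marlintrack:::project_obs(obs)
    oracle <- dense_ctcrw_loglik_1d(pr$t, pr$x, sds$sd_lon_km, beta, sigma) +
      dense_ctcrw_loglik_1d(pr$t, pr$y, sds$sd_lat_km, beta, sigma)
    expect_lt(abs(kf$loglik - oracle) / abs(oracle), 1e-8)
  }
})

test_that("an observation with enormous variance is non-informative", {
  set.seed(22)
  n <- 12
  t <- sort(runif(n, 0, 20))
  y <- cumsum(rnorm(n, 0, 5))
  sd <- rep(1, n)
  full <- marlintrack:::kf_1d(t, y, sd, 0.8, 10)
  sd_inf <- sd; sd_inf[6] <- 1e6
  infl <- marlintrack:::kf_1d(t, y, sd_inf, 0.8, 10)
  drop6 <- marlintrack:::kf_1d(t[-6], y[-6], sd[-6], 0.8, 10)
  # likelihood differs only by the (flat) term of the inflated observation
  flat <- dnorm(0, 0, sqrt(infl$Pp[6, 1, 1] + 1e12), log = TRUE) +
    -0.5 * (y[6] - infl$mp[6, 1])^2 / (infl$Pp[6, 1, 1] + 1e12)
  expect_lt(abs((infl$loglik - flat) - drop6$loglik), 1e-6 * abs(drop6$loglik))
  # filtered states elsewhere match the deleted-observation filter
  expect_equal(infl$mf[n, 1], drop6$mf[n - 1, 1], tolerance = 1e-6)
})

test_that("error_scale is an exact multiplier on measurement SDs", {
  set.seed(23)
  n <- 15
  t <- sort(runif(n, 0, 30))
  cls <- sample(c("3", "1", "B"), n, replace = TRUE)
  xy <- simulate_ctcrw(t, ctcrw_params(1, 20))
  obs <- obs_from_planar(t, xy$x, xy$y, cls)
  err1 <- error_model()
  err2 <- error_model(base_sd_lon_km = 1, base_sd_lat_km = 1)  # doubled
  l1 <- kalman_filter(obs, ctcrw_params(1, 20, error_scale = 1), err1)$loglik
  l2 <- kalman_filter(obs, ctcrw_params(1, 20, error_scale = 0.5), err2)$loglik
  expect_equal(l1, l2, tolerance = 1e-12)
})

test_that("ML fit recovers generating parameters and beats its start", {
  set.seed(24)
  err <- error_model()
  rel_err <- t(sapply(1:5, function(r) {
    n <- 200
    t <- sort(runif(n, 0, 80))
    cls <- sample(c("3", "2", "1"), n, replace = TRUE)
    xy <- simulate_ctcrw(t, ctcrw_params(0.8, 30))
    sds <- obs_error_sd(err, cls)
    obs <- obs_from_planar(t, xy$x + rnorm(n, 0, sds$sd_lon_km),
                           xy$y + rnorm(n, 0, sds$sd_lat_km), cls)
    f <- fit_ctcrw(obs, err)
    expect_true(f$converged)
    # fitted likelihood at least matches the truth's likelihood
    l_true <- kalman_filter(obs, ctcrw_params(0.8, 30), err)$loglik
    expect_gte(f$loglik, l_true - 1e-6)
    # refit from a different start reaches the same optimum
    f2 <- fit_ctcrw(obs, err, init = ctcrw_params(0.2, 80))
    expect_lt(abs(f2$params$beta - f$params$beta) / f$params$beta, 1e-3)
    c(abs(f$params$beta - 0.8) / 0.8, abs(f$params$sigma - 30) / 30)
  }))
  expect_lt(median(rel_err[, 1]), 0.3)
  expect_lt(median(rel_err[, 2]), 0.15)
})

test_that("smoother interpolates observations and widens in gaps", {
  set.seed(25)
  t <- c(seq(0, 10, 0.4), seq(20, 30, 0.4))   # 10-day central gap
  n <- length(t)
  xy <- simulate_ctcrw(t, ctcrw_params(1, 15))
  tiny <- error_model(base_sd_lon_km = 1e-4, base_sd_lat_km = 1e-4)
  obs <- obs_from_planar(t, xy$x, xy$y, rep("3", n))
  tr <- smooth_predict(obs, ctcrw_params(1, 15), tiny,
                       grid = regular_grid(obs))
  # near-zero measurement error: smoothed position at an observation time
  # reproduces the observation
  g_on_obs <- which(abs(outer(tr$t, obs$t, "-")) < 1e-9, arr.ind = TRUE)
  i <- g_on_obs[1, 1]; j <- g_on_obs[1, 2]
  d <- haversine_km(tr$lon[i], tr$lat[i], obs$lon[j], obs$lat[j])
  expect_lt(d, 1e-5)
  # SD larger deep inside the gap than near an observation
  sd_gap <- tr$sd_km[which.min(abs(tr$t - 15))]
  sd_near <- tr$sd_km[which.min(abs(tr$t - 9.9))]
  expect_gt(sd_gap, sd_near)
  expect_true(all(tr$sd_km >= 0))
  expect_equal(unique(round(diff(tr$t), 9)), 0.5)
  # gap rows flagged low-confidence only for spans beyond the threshold
  tr8 <- smooth_predict(obs, ctcrw_params(1, 15), tiny,
                        gap_threshold_days = 8)
  expect_true(any(tr8$low_confidence[tr8$t > 10 & tr8$t < 20]))
  expect_false(any(tr8$low_confidence[tr8$t < 10]))
  # no extrapolation
  expect_error(smooth_predict(obs, ctcrw_params(1, 15), tiny,
                              grid = seq(-1, 5, 0.5)), "span")
})

test_that("smoothing is a projection and grid times carry no information", {
  set.seed(26)
  t <- sort(runif(40, 0, 20))
  xy <- simulate_ctcrw(t, ctcrw_params(1, 15))
  err <- error_model()
  obs <- obs_from_planar(t, xy$x + rnorm(40, 0, 0.5), xy$y + rnorm(40, 0, 0.5),
                         rep("3", 40))
  pars <- ctcrw_params(1, 15)
  grid <- regular_grid(obs)
  tr <- smooth_predict(obs, pars, err, grid = grid)
  # projection: re-smoothing the smoothed means with tiny error reproduces them
  tiny <- error_model(base_sd_lon_km = 1e-5, base_sd_lat_km = 1e-5)
  obs2 <- obs_from_planar(tr$t, tr$x_km, tr$y_km, rep("3", nrow(tr)),
                          center = unlist(attr(tr, "center")))
  tr2 <- smooth_predict(obs2, pars, tiny, grid = grid)
  # compare in geographic coordinates (the two runs centre their projections
  # differently)
  expect_lt(max(haversine_km(tr2$lon, tr2$lat, tr$lon, tr$lat)), 0.01)
  # invariance: adding extra grid times does not move shared predictions
  dense <- sort(unique(c(grid, grid[-length(grid)] + 0.25)))
  tr3 <- smooth_predict(obs, pars, err, grid = dense)
  shared <- match(grid, tr3$t)
  expect_equal(tr3$x_km[shared], tr$x_km, tolerance = 1e-9)
  expect_equal(tr3$sd_km[shared], tr$sd_km, tolerance = 1e-9)
})

test_that("coordinatewise RMS error behaves as defined", {
  a <- data.frame(lon = c(176, 177, 178), lat = c(-37, -36, -35))
  expect_equal(unname(rms_error_km(a, a)), c(0, 0))
  b <- a
  b$lat <- b$lat + 1 / (marlintrack:::EARTH_RADIUS_KM * pi / 180)  # +1 km north
  expect_equal(unname(rms_error_km(b, a)), c(0, 1), tolerance = 1e-9)
  expect_error(rms_error_km(a, a[1:2, ]), "mismatch")
  # LLN: Gaussian latitude noise of SD 10 km -> rms_lat within 2% of 10
  set.seed(27)
  n <- 10000
  tru <- data.frame(lon = rep(180, n), lat = runif(n, -40, -20))
  est <- tru
  est$lat <- est$lat + rnorm(n, 0, 10) / (marlintrack:::EARTH_RADIUS_KM * pi / 180)
  expect_lt(abs(rms_error_km(est, tru)[["rms_lat_km"]] - 10) / 10, 0.02)
})
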