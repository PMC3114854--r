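test_that("step metrics compute speeds, turns and headings on the sphere", {
  # equally spaced collinear points along a meridian: zero turn, equal speeds
  tr <- data.frame(t = c(0, 0.5, 1), lon = rep(176, 3),
                   lat = c(-37, -36.9, -36.8))
  st <- step_metrics(tr)
  expect_equal(nrow(st), 2L)
  expect_true(is.na(st$turn_rad[1]))
  expect_equal(st$turn_rad[2], 0, tolerance = 1e-9)
  expect_equal(st$speed_kmh[1], st$speed_kmh[2], tolerance = 1e-6)

  # exact reversal (along the equator, where the return bearing is exactly
  # opposite) maps to +pi by the wrap convention
  tr2 <- data.frame(t = c(0, 0.5, 1), lon = c(176, 177, 176),
                    lat = c(0, 0, 0))
  st2 <- step_metrics(tr2)
  expect_equal(st2$turn_rad[2], pi, tolerance = 1e-9)

  # 11.1195 km per 12-h step -> 0.927 km/h
  dlat <- 11.1195 / (marlintrack:::EARTH_RADIUS_KM * pi / 180)
  tr3 <- data.frame(t = c(0, 0.5, 1), lon = rep(180, 3),
                    lat = -37 + c(0, dlat, 2 * dlat))
  st3 <- step_metrics(tr3)
  expect_equal(st3$speed_kmh, rep(11.1195 / 12, 2), tolerance = 1e-4)

  expect_error(step_metrics(tr[1:2, ]), "3 positions")
})

test_that("EM recovers well-separated mixture components", {
  set.seed(31)
  n <- 500
  res <- sapply(1:10, function(r) {
    comp <- sample(1:4, n, replace = TRUE, prob = c(0.3, 0.3, 0.25, 0.15))
    mu <- c(0.7, 1.9)[ifelse(comp %in% c(2, 4), 2, 1)]
    v <- rgamma(n, shape = 16, rate = 16 / mu)
    rho <- c(0.8, 0.1)[ifelse(comp %in% c(3, 4), 2, 1)]
    th <- numeric(n)
    for (k in unique(rho)) {
      ix <- rho == k
      th[ix] <- marlintrack:::rwrapped_cauchy(sum(ix), k)
    }
    st <- data.frame(animal_id = "a", t0 = seq_len(n) * 0.5 - 0.5,
                     t1 = seq_len(n) * 0.5, speed_kmh = v, turn_rad = th,
                     heading_rad = 0, valid = TRUE)
    fit <- fit_movement_mixture(st, n_restarts = 10, seed = r)
    means <- fit$speed_shape / fit$speed_rate
    realized <- as.vector(table(factor(comp, 1:4)) / n)
    c(m1 = abs(means[1] - 0.7) / 0.7,
      m2 = abs(means[2] - 1.9) / 1.9,
      rho_dir = abs(fit$angle_rho[1] - 0.8),
      wmax = max(abs(fit$weights - realized)))
  })
  # speed component means within 10% on every replicate
  expect_true(all(res["m1", ] < 0.1))
  expect_true(all(res["m2", ] < 0.1))
  # directed concentration recovered
  expect_true(all(res["rho_dir", ] < 0.1))
  # weights: typical error below 0.05; the tortuous concentration is weakly
  # identified at this overlap, which caps worst-case weight error near 0.08
  expect_lt(median(res["wmax", ]), 0.05)
  expect_true(all(res["wmax", ] < 0.08))
})

test_that("EM log-likelihood trace is monotone and degeneracy is flagged", {
  set.seed(32)
  n <- 200
  v <- rgamma(n, 10, 10 / 1.2)
  th <- marlintrack:::rwrapped_cauchy(n, 0.5)
  st <- data.frame(animal_id = "a", t0 = seq_len(n) * 0.5 - 0.5,
                   t1 = seq_len(n) * 0.5, speed_kmh = v, turn_rad = th,
                   heading_rad = 0, valid = TRUE)
  fit <- fit_movement_mixture(st, n_restarts = 5, seed = 1)
  trace <- attr(fit, "ll_trace")
  expect_gt(length(trace), 1)
  expect_true(all(diff(trace) > -1e-6 * abs(trace[-length(trace)])))

  # constant data: degenerate flag raised
  stc <- st
  stc$speed_kmh <- 1
  stc$turn_rad <- 0
  fitc <- fit_movement_mixture(stc, n_restarts = 2, seed = 1)
  expect_true(fitc$degenerate)

  expect_error(fit_movement_mixture(st[1:10, ]), "30 valid steps")
})

test_that("classification assigns modes by component likelihood", {
  par <- marlintrack:::new_mixture_params(
    speed_shape = c(16, 16), speed_rate = c(16 / 0.7, 16 / 1.9),
    angle_rho = c(0.8, 0.1), weights = rep(0.25, 4))
  st <- data.frame(animal_id = "a", t0 = c(0, 0.5, 1), t1 = c(0.5, 1, 1.5),
                   speed_kmh = c(1.9, 0.7, 1.0), turn_rad = c(0.05, 2.8, 0.1),
                   heading_rad = 0, valid = TRUE)
  ms <- classify_steps(st, par)
  expect_equal(ms$mode[1], 2L)   # fast, directed
  expect_equal(ms$mode[2], 3L)   # slow, tortuous
  expect_false(ms$error_dominated[1])

  # exactly equal likelihoods break towards the lower mode: a symmetric
  # construction with identical speed components
  par_tie <- marlintrack:::new_mixture_params(
    speed_shape = c(16, 16), speed_rate = c(16, 16),
    angle_rho = c(0.5, 0.5), weights = rep(0.25, 4))
  ms_tie <- classify_steps(st, par_tie)
  expect_true(all(ms_tie$mode == 1L))

  # invalid steps stay unassigned
  st$valid[2] <- FALSE
  ms2 <- classify_steps(st, par)
  expect_true(is.na(ms2$mode[2]))
})

test_that("classification is invariant to rigid rotation and time shift", {
  set.seed(33)
  n <- 60
  sp <- rgamma(n, 10, 10 / 1.2)
  turns <- marlintrack:::rwrapped_cauchy(n, 0.6)
  build <- function(h0, t0) {
    lon <- numeric(n + 1); lat <- numeric(n + 1)
    lon[1] <- 190; lat[1] <- -30
    h <- h0 + cumsum(turns)
    for (i in seq_len(n)) {
      p <- marlintrack:::destination_point(lon[i], lat[i], h[i], sp[i] * 12)
      lon[i + 1] <- p$lon; lat[i + 1] <- p$lat
    }
    data.frame(t = t0 + (0:n) * 0.5, lon = lon, lat = lat)
  }
  par <- marlintrack:::new_mixture_params(
    speed_shape = c(16, 16), speed_rate = c(16 / 0.7, 16 / 1.9),
    angle_rho = c(0.8, 0.1), weights = rep(0.25, 4))
  m1 <- classify_steps(step_metrics(build(0.3, 0)), par)
  m2 <- classify_steps(step_metrics(build(2.1, 100)), par)
  expect_gt(mean(m1$mode == m2$mode, na.rm = TRUE), 0.95)
})

test_that("run-length smoothing absorbs short runs and is idempotent", {
  mk <- function(m) {
    d <- data.frame(animal_id = "a", t0 = seq_along(m) * 0.5 - 0.5,
                    t1 = seq_along(m) * 0.5, mode = as.integer(m),
                    error_dominated = FALSE)
    class(d) <- c("mode_sequence", "data.frame")
    d
  }
  expect_equal(smooth_modes(mk(c(2, 2, 3, 2, 2)), 1)$mode,
               c(2L, 2L, 3L, 2L, 2L))
  expect_equal(smooth_modes(mk(c(2, 2, 3, 2, 2)), 2)$mode, rep(2L, 5))
  set.seed(34)
  for (r in 1:20) {
    m <- sample(1:4, 40, replace = TRUE)
    m[sample(40, 4)] <- NA
    mr <- sample(2:4, 1)
    once <- smooth_modes(mk(m), mr)$mode
    twice <- smooth_modes(smooth_modes(mk(m), mr), mr)$mode
    expect_identical(twice, once)
  }
})

test_that("bout statistics match hand counts and conserve duration", {
  mk <- function(m) {
    d <- data.frame(animal_id = "a", t0 = seq_along(m) * 0.5 - 0.5,
                    t1 = seq_along(m) * 0.5, mode = as.integer(m),
                    error_dominated = FALSE)
    class(d) <- c("mode_sequence", "data.frame")
    d
  }
  b0 <- bout_statistics(mk(rep(1, 10)))
  expect_equal(length(b0$bout_days), 0L)
  expect_equal(length(b0$interval_days), 0L)

  b <- bout_statistics(mk(c(1, 3, 3, 3, 1, 1, 1, 1, 3, 3)))
  expect_equal(b$bout_days, c(1.5, 1.0))
  expect_equal(b$interval_days, 2.0)

  # durations + intervals + leading/trailing non-ARB = total
  set.seed(35)
  for (r in 1:10) {
    m <- sample(c(1, 2, 3, 4), 60, replace = TRUE)
    bb <- bout_statistics(mk(m))
    arb <- m %in% c(3, 4)
    rr <- rle(arb)
    lead <- if (!rr$values[1]) rr$lengths[1] * 0.5 else 0
    trail <- if (!rr$values[length(rr$values)] && length(rr$lengths) > 1)
      rr$lengths[length(rr$lengths)] * 0.5 else 0
    expect_equal(sum(bb$bout_days) + sum(bb$interval_days) + lead + trail,
                 30)
  }
})

test_that("generator bout targets are recovered through classification", {
  set.seed(36)
  est_bouts <- numeric(0)
  true_bouts <- numeric(0)
  for (r in 1:8) {
    cfg <- separated_sim_config(seed = 400 + r, duration_days = 150)
    s <- simulate_track(cfg, geolocation = FALSE, err = error_model())
    grid <- seq(0.5, 149.5, 0.5)
    tp <- marlintrack:::interp_path(s$truth, grid)
    tp$low_confidence <- FALSE
    st <- step_metrics(tp)
    mp <- fit_movement_mixture(st, n_restarts = 10, seed = r)
    # a 2-day minimum run keeps single misclassified steps from splitting
    # multi-day bouts in half
    ms <- smooth_modes(classify_steps(st, mp, window_steps = 5), 4)
    est_bouts <- c(est_bouts, bout_statistics(ms)$bout_days)
    # realized truth at the same 12-h sampling (bouts censored by the record
    # ends exactly as the estimate is)
    truth <- true_mode_per_step(st, s$modes)
    tms <- ms
    tms$mode <- truth
    true_bouts <- c(true_bouts, bout_statistics(tms)$bout_days)
  }
  # pooled mean ARB bout duration within 25% of the realized truth
  expect_lt(abs(mean(est_bouts) / mean(true_bouts) - 1), 0.25)
})
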