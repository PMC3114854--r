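# Continuous-time correlated random walk (CTCRW) state-space model.
#
# Per planar coordinate the state is (position, velocity) with
# Ornstein-Uhlenbeck velocity: dv = -beta v dt + sigma dW. Between two times
# separated by dt the exact discretization is linear-Gaussian, so irregular
# observation times cost nothing: the Kalman filter runs on the observation
# times directly and the smoother is evaluated on any extra prediction grid.

#' CTCRW parameters
#'
#' @param beta velocity autocorrelation rate (1/day, > 0); 1/beta is the
#'   velocity decorrelation time.
#' @param sigma velocity diffusion scale (km/day^1.5, > 0); the stationary
#'   velocity SD is sigma/sqrt(2 beta).
#' @param error_scale free multiplier (>= 0) on the error-model measurement
#'   SDs; fixed at 1 unless estimated.
#' @return object of class \code{ctcrw_params}.
#' @export
ctcrw_params <- function(beta, sigma, error_scale = 1) {
  stopifnot(is.finite(beta), beta > 0, is.finite(sigma), sigma > 0,
            is.finite(error_scale), error_scale >= 0)
  structure(list(beta = beta, sigma = sigma, error_scale = error_scale),
            class = "ctcrw_params")
}

#' Exact CTCRW transition and process covariance
#'
#' Closed-form discretization of the OU-velocity model over a step of
#' \code{dt} days, per coordinate, for state (position, velocity):
#' \deqn{x_{t+dt} = x_t + v_t (1-e^{-\beta dt})/\beta + \xi, \quad
#'       v_{t+dt} = e^{-\beta dt} v_t + \zeta}
#' with \eqn{Var(\zeta) = \sigma^2 (1-e^{-2\beta dt})/(2\beta)},
#' \eqn{Var(\xi) = \sigma^2/\beta^2 [dt - 2(1-e^{-\beta dt})/\beta +
#' (1-e^{-2\beta dt})/(2\beta)]} and
#' \eqn{Cov(\xi,\zeta) = \sigma^2 (1 - 2e^{-\beta dt} + e^{-2\beta dt}) /
#' (2\beta^2)}.
#'
#' @param params a [ctcrw_params()].
#' @param dt time step in days (>= 0).
#' @return list with 2x2 matrices \code{Phi} (transition) and \code{Q}
#'   (process covariance).
#' @export
ctcrw_matrices <- function(params, dt) {
  stopifnot(length(dt) == 1, is.finite(dt))
  if (dt < 0) stop("dt must be >= 0")
  b <- params$beta; s2 <- params$sigma^2
  e1 <- exp(-b * dt); e2 <- exp(-2 * b * dt)
  Phi <- matrix(c(1, 0, (1 - e1) / b, e1), 2, 2)
  var_x <- s2 / b^2 * (dt - 2 * (1 - e1) / b + (1 - e2) / (2 * b))
  var_v <- s2 * (1 - e2) / (2 * b)
  cov_xv <- s2 / (2 * b^2) * (1 - 2 * e1 + e2)
  Q <- matrix(c(var_x, cov_xv, cov_xv, var_v), 2, 2)
  list(Phi = Phi, Q = Q)
}

#' Simulate a CTCRW exactly at given times
#'
#' Draws one realization of the model (two independent coordinates) at the
#' supplied times using the exact discretization; used for parameter-recovery
#' experiments and residual diagnostics.
#'
#' @param times increasing numeric vector (days).
#' @param params a [ctcrw_params()].
#' @param x0 initial position (km, length 2).
#' @param v0 initial velocity (km/day, length 2); default draws from the
#'   stationary velocity distribution.
#' @return data.frame with columns \code{t, x, y, vx, vy} (km, km/day).
#' @export
simulate_ctcrw <- function(times, params, x0 = c(0, 0), v0 = NULL) {
  stopifnot(!is.unsorted(times))
  n <- length(times)
  if (is.null(v0)) {
    sdv <- params$sigma / sqrt(2 * params$beta)
    v0 <- stats::rnorm(2, 0, sdv)
  }
  out <- matrix(0, n, 4)
  st <- rbind(c(x0[1], v0[1]), c(x0[2], v0[2]))  # rows: coord; cols: (x, v)
  out[1, ] <- c(st[, 1], st[, 2])
  if (n > 1) {
    for (i in 2:n) {
      mats <- ctcrw_matrices(params, times[i] - times[i - 1])
      L <- chol_psd(mats$Q)
      for (k in 1:2) {
        st[k, ] <- drop(mats$Phi %*% st[k, ]) + drop(L %*% stats::rnorm(2))
      }
      out[i, ] <- c(st[, 1], st[, 2])
    }
  }
  data.frame(t = times, x = out[, 1], y = out[, 2],
             vx = out[, 3], vy = out[, 4])
}

# Lower Cholesky factor tolerant of semi-definite matrices (dt = 0 gives Q = 0).
chol_psd <- function(M) {
  ev <- eigen(M, symmetric = TRUE)
  v <- pmax(ev$values, 0)
  ev$vectors %*% diag(sqrt(v), nrow = length(v))
}

# One-coordinate Kalman filter over (possibly missing) observations.
# t: times (days), y: observations (km; NA = predict only), sd: measurement SD.
# Prior: position at first observed y with its measurement variance; diffuse
# velocity (variance v0_var). Returns stored quantities for the RTS smoother.
kf_1d <- function(t, y, sd, beta, sigma, v0_var = 1e6) {
  n <- length(t)
  p <- ctcrw_params(beta, sigma)
  i1 <- which(!is.na(y))[1]
  if (is.na(i1)) stop("no observations")
  m0 <- c(y[i1], 0)
  P0 <- diag(c(sd[i1]^2, v0_var))
  mp <- matrix(NA_real_, n, 2); mf <- matrix(NA_real_, n, 2)
  Pp <- array(NA_real_, c(n, 2, 2)); Pf <- array(NA_real_, c(n, 2, 2))
  Phis <- array(NA_real_, c(n, 2, 2))
  ll <- 0
  m <- m0; P <- P0
  for (i in seq_len(n)) {
    if (i == 1) {
      mpi <- m0; Ppi <- P0
      Phis[i, , ] <- diag(2)
    } else {
      mats <- ctcrw_matrices(p, t[i] - t[i - 1])
      Phis[i, , ] <- mats$Phi
      mpi <- drop(mats$Phi %*% m)
      Ppi <- mats$Phi %*% P %*% t(mats$Phi) + mats$Q
    }
    mp[i, ] <- mpi; Pp[i, , ] <- Ppi
    if (!is.na(y[i])) {
      S <- Ppi[1, 1] + sd[i]^2
      if (!is.finite(S) || S <= 0)
        stop("singular innovation covariance at time index ", i)
      v <- y[i] - mpi[1]
      ll <- ll + stats::dnorm(v, 0, sqrt(S), log = TRUE)
      K <- Ppi[, 1] / S
      m <- mpi + K * v
      P <- Ppi - outer(K, Ppi[1, ])
      P <- (P + t(P)) / 2
    } else {
      m <- mpi; P <- Ppi
    }
    mf[i, ] <- m; Pf[i, , ] <- P
  }
  list(loglik = ll, t = t, mp = mp, Pp = Pp, mf = mf, Pf = Pf, Phis = Phis)
}

# RTS fixed-interval smoother on a kf_1d result.
ks_1d <- function(kf) {
  n <- length(kf$t)
  ms <- kf$mf; Ps <- kf$Pf
  if (n > 1) {
    for (i in (n - 1):1) {
      Ppn <- kf$Pp[i + 1, , ]
      Ppn_inv <- tryCatch(solve(Ppn), error = function(e)
        solve(Ppn + diag(1e-10 * max(diag(Ppn), 1e-12), 2)))
      J <- kf$Pf[i, , ] %*% t(kf$Phis[i + 1, , ]) %*% Ppn_inv
      ms[i, ] <- kf$mf[i, ] + drop(J %*% (ms[i + 1, ] - kf$mp[i + 1, ]))
      Ps[i, , ] <- kf$Pf[i, , ] + J %*% (Ps[i + 1, , ] - Ppn) %*% t(J)
    }
  }
  list(t = kf$t, ms = ms, Ps = Ps)
}

# Project a single-animal observation set to planar km around its centroid.
project_obs <- function(obs, center = NULL) {
  stopifnot(nrow(obs) >= 1)
  if (length(unique(obs$animal_id)) > 1)
    stop("expected observations from a single animal")
  if (is.null(center)) center <- track_centroid(obs$lon, obs$lat)
  xy <- project_aeqd(obs$lon, obs$lat, center$lon, center$lat)
  list(center = center, t = obs$t, x = xy$x, y = xy$y)
}

#' Kalman filter log-likelihood for one animal
#'
#' Projects the observations to a local planar frame, runs the exact-
#' discretization Kalman filter independently on the east and north
#' coordinates with class-specific measurement SDs, and returns the
#' prediction-error-decomposition log-likelihood plus filtered states.
#'
#' @param obs single-animal \code{observation_set} (>= 2 rows).
#' @param params a [ctcrw_params()].
#' @param err an [error_model()].
#' @param v0_var diffuse velocity prior variance (km^2/day^2).
#' @return list with \code{loglik}, \code{center}, and per-coordinate filter
#'   outputs \code{kx}, \code{ky}.
#' @export
kalman_filter <- function(obs, params, err, v0_var = 1e6) {
  if (nrow(obs) < 2) stop("need at least 2 observations")
  if (any(!is.finite(obs$t)) || any(!is.finite(obs$lon)) || any(!is.finite(obs$lat)))
    stop("non-finite observation values")
  pr <- project_obs(obs)
  sds <- obs_error_sd(err, obs$loc_class, params$error_scale)
  kx <- kf_1d(pr$t, pr$x, sds$sd_lon_km, params$beta, params$sigma, v0_var)
  ky <- kf_1d(pr$t, pr$y, sds$sd_lat_km, params$beta, params$sigma, v0_var)
  list(loglik = kx$loglik + ky$loglik, center = pr$center, kx = kx, ky = ky)
}

#' Fit CTCRW parameters by maximum likelihood
#'
#' Bounded quasi-Newton (L-BFGS-B) optimisation of the filter log-likelihood
#' over log(beta) and log(sigma) (and optionally log(error_scale)).
#' Deterministic given data and init.
#'
#' @param obs single-animal \code{observation_set}; >= 20 observations
#'   recommended for stable estimates.
#' @param err an [error_model()].
#' @param init starting [ctcrw_params()].
#' @param bounds list with \code{lower}, \code{upper} on (beta, sigma) scale.
#' @param estimate_error_scale also estimate the free error multiplier
#'   (default FALSE: fixed at \code{init$error_scale}).
#' @return list with \code{params} (fitted [ctcrw_params()]), \code{loglik},
#'   \code{converged}, \code{vcov_log} (covariance of the log-parameters from
#'   the numerical Hessian; NULL if not available), and \code{diagnostics}
#'   (the raw optimizer result).
#' @export
fit_ctcrw <- function(obs, err, init = ctcrw_params(1, 20),
                      bounds = list(lower = c(1e-4, 1e-4), upper = c(1e4, 1e4)),
                      estimate_error_scale = FALSE) {
  pr <- project_obs(obs)
  sds <- obs_error_sd(err, obs$loc_class, 1)
  nll <- function(lp) {
    beta <- exp(lp[1]); sigma <- exp(lp[2])
    esc <- if (estimate_error_scale) exp(lp[3]) else init$error_scale
    ll <- tryCatch(
      kf_1d(pr$t, pr$x, sds$sd_lon_km * esc, beta, sigma)$loglik +
        kf_1d(pr$t, pr$y, sds$sd_lat_km * esc, beta, sigma)$loglik,
      error = function(e) -Inf)
    if (!is.finite(ll)) 1e10 else -ll
  }
  lp0 <- log(c(init$beta, init$sigma))
  lo <- log(bounds$lower); hi <- log(bounds$upper)
  if (estimate_error_scale) {
    lp0 <- c(lp0, log(max(init$error_scale, 1e-3)))
    lo <- c(lo, log(1e-3)); hi <- c(hi, log(1e3))
  }
  opt <- stats::optim(lp0, nll, method = "L-BFGS-B", lower = lo, upper = hi,
                      hessian = TRUE,
                      control = list(maxit = 500, factr = 1e-8 / .Machine$double.eps))
  fitted <- ctcrw_params(exp(opt$par[1]), exp(opt$par[2]),
                         if (estimate_error_scale) exp(opt$par[3]) else init$error_scale)
  vcov_log <- tryCatch(solve(opt$hessian), error = function(e) NULL)
  list(params = fitted, loglik = -opt$value,
       converged = opt$convergence == 0,
       vcov_log = vcov_log, diagnostics = opt)
}

#' Regular 12-h prediction grid for an observation span
#'
#' Times (decimal days since release) at multiples of \code{step_days} inside
#' the observation span. With release at 00:00 UTC these are the 00:00/12:00
#' anchor times.
#'
#' @param obs single-animal \code{observation_set}.
#' @param step_days grid spacing in days (default 0.5 = 12 h).
#' @return numeric vector of grid times.
#' @export
regular_grid <- function(obs, step_days = 0.5) {
  t0 <- min(obs$t); t1 <- max(obs$t)
  seq(ceiling(t0 / step_days) * step_days,
      floor(t1 / step_days) * step_days, by = step_days)
}

#' Smooth a track onto a regular grid
#'
#' Runs the forward filter and RTS fixed-interval smoother on the union of
#' observation and grid times and returns the grid rows: smoothed positions
#' (back-projected to lon/lat), positional SD, distance in days to the nearest
#' observation, and a low-confidence flag for grid times that fall inside an
#' observation gap longer than \code{gap_threshold_days}. No extrapolation:
#' the grid must lie within the observation span.
#'
#' @param obs single-animal \code{observation_set}.
#' @param params fitted [ctcrw_params()].
#' @param err an [error_model()].
#' @param grid increasing times in days; default [regular_grid()] at 12 h.
#' @param gap_threshold_days gap length (days) beyond which intervening grid
#'   rows are flagged low-confidence rather than dropped.
#' @return a \code{regular_track}: data.frame with columns \code{animal_id, t,
#'   lon, lat, x_km, y_km, sd_km, gap_days, low_confidence}; the projection
#'   centre is stored in attribute \code{center}.
#' @export
smooth_predict <- function(obs, params, err, grid = regular_grid(obs),
                           gap_threshold_days = 20) {
  stopifnot(!is.unsorted(grid))
  if (length(grid) < 1) stop("empty prediction grid")
  if (min(grid) < min(obs$t) - 1e-9 || max(grid) > max(obs$t) + 1e-9)
    stop("prediction grid extends outside the observation span")
  pr <- project_obs(obs)
  sds <- obs_error_sd(err, obs$loc_class, params$error_scale)
  tt <- c(pr$t, grid)
  yx <- c(pr$x, rep(NA_real_, length(grid)))
  yy <- c(pr$y, rep(NA_real_, length(grid)))
  sx <- c(sds$sd_lon_km, rep(NA_real_, length(grid)))
  sy <- c(sds$sd_lat_km, rep(NA_real_, length(grid)))
  ord <- order(tt, is.na(yx))  # observations first at exactly coincident times
  tt <- tt[ord]; yx <- yx[ord]; yy <- yy[ord]; sx <- sx[ord]; sy <- sy[ord]
  smx <- ks_1d(kf_1d(tt, yx, sx, params$beta, params$sigma))
  smy <- ks_1d(kf_1d(tt, yy, sy, params$beta, params$sigma))
  # each grid time has a dedicated NA-observation row, even when it coincides
  # with an observation time (dt = 0 between the two rows is exact: Phi = I,
  # Q = 0), so the smoothed state there is well defined
  grid_rows <- which(is.na(yx))
  idx <- grid_rows[match(grid, tt[grid_rows])]
  x <- smx$ms[idx, 1]; y <- smy$ms[idx, 1]
  sd_km <- sqrt(pmax(smx$Ps[idx, 1, 1], 0) + pmax(smy$Ps[idx, 1, 1], 0))
  ll <- unproject_aeqd(x, y, pr$center$lon, pr$center$lat)
  gap_days <- vapply(grid, function(g) min(abs(pr$t - g)), numeric(1))
  # length of the inter-observation interval each grid time falls into
  span <- vapply(grid, function(g) {
    lo <- suppressWarnings(max(pr$t[pr$t <= g + 1e-9]))
    hi <- suppressWarnings(min(pr$t[pr$t >= g - 1e-9]))
    if (!is.finite(lo) || !is.finite(hi)) Inf else hi - lo
  }, numeric(1))
  out <- data.frame(animal_id = obs$animal_id[1], t = grid,
                    lon = ll$lon, lat = ll$lat, x_km = x, y_km = y,
                    sd_km = sd_km, gap_days = gap_days,
                    low_confidence = span > gap_threshold_days)
  attr(out, "center") <- pr$center
  attr(out, "params") <- params
  class(out) <- c("regular_track", "data.frame")
  out
}

#' Coordinatewise RMS error between two tracks
#'
#' Great-circle-consistent per-axis displacements: the longitude component is
#' measured along the parallel at the mean latitude of each pair, the latitude
#' component along the meridian.
#'
#' @param estimate,truth data.frames with columns \code{lon}, \code{lat} on a
#'   common time grid (equal row counts).
#' @return named numeric: \code{rms_lon_km}, \code{rms_lat_km}.
#' @export
rms_error_km <- function(estimate, truth) {
  if (nrow(estimate) != nrow(truth)) stop("track length mismatch")
  dlon <- ((estimate$lon - truth$lon + 180) %% 360) - 180
  mlat <- (estimate$lat + truth$lat) / 2
  ex <- EARTH_RADIUS_KM * .deg2rad(dlon) * cos(.deg2rad(mlat))
  ey <- EARTH_RADIUS_KM * .deg2rad(estimate$lat - truth$lat)
  c(rms_lon_km = sqrt(mean(ex^2)), rms_lat_km = sqrt(mean(ey^2)))
}
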