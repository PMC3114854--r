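# Four-mode pseudo-behavioural classification of regularized 12-h steps.
# Modes are the Cartesian product of two speed components (gamma densities,
# slow/fast) and two turning-angle components (wrapped Cauchy, mean 0,
# directed/tortuous):
#   1 slow-transit  = slow  x directed
#   2 fast-transit  = fast  x directed
#   3 slow-ARB      = slow  x tortuous
#   4 fast-ARB      = fast  x tortuous
# Mode 4 (fast + tortuous) is flagged as error-dominated: sustained fast,
# highly tortuous movement is more plausibly a run of high location error
# than a biological state.

#' Step metrics from a regular track
#'
#' Speeds (great-circle displacement over the step, km/h), signed turning
#' angles (difference of successive bearings wrapped to (-pi, pi]; exact
#' reversals map to +pi), and absolute headings. A step is invalid when either
#' bounding position is flagged low-confidence; the first step's turning angle
#' is undefined.
#'
#' @param track a \code{regular_track} (or data.frame with \code{t, lon, lat}
#'   and optional \code{low_confidence}), >= 3 positions at constant spacing.
#' @return a \code{step_series}: data.frame with one row per step (between
#'   positions i and i+1): \code{t0, t1, speed_kmh, turn_rad, heading_rad,
#'   valid}.
#' @export
step_metrics <- function(track) {
  n <- nrow(track)
  if (n < 3) stop("need at least 3 positions")
  lc <- if ("low_confidence" %in% names(track)) track$low_confidence else
    rep(FALSE, n)
  i <- seq_len(n - 1)
  dist <- haversine_km(track$lon[i], track$lat[i],
                       track$lon[i + 1], track$lat[i + 1])
  dt_h <- diff(track$t) * 24
  heading <- bearing_rad(track$lon[i], track$lat[i],
                         track$lon[i + 1], track$lat[i + 1])
  turn <- c(NA_real_, wrap_angle(diff(heading)))
  out <- data.frame(animal_id = if ("animal_id" %in% names(track))
                      track$animal_id[i] else "track",
                    t0 = track$t[i], t1 = track$t[i + 1],
                    speed_kmh = dist / dt_h,
                    turn_rad = turn,
                    heading_rad = heading,
                    valid = !(lc[i] | lc[i + 1]))
  class(out) <- c("step_series", "data.frame")
  out
}

# log wrapped-Cauchy density, mean 0, concentration rho in [0, 1)
dwrapped_cauchy_log <- function(theta, rho) {
  log1p(-rho^2) - log(2 * pi) - log(1 + rho^2 - 2 * rho * cos(theta))
}

# per-component log density of (speed, turn); component order = mode order
component_loglik <- function(speed, turn, par) {
  sp <- pmax(speed, 1e-6)
  ls <- cbind(stats::dgamma(sp, par$speed_shape[1], par$speed_rate[1], log = TRUE),
              stats::dgamma(sp, par$speed_shape[2], par$speed_rate[2], log = TRUE))
  la <- cbind(dwrapped_cauchy_log(turn, par$angle_rho[1]),
              dwrapped_cauchy_log(turn, par$angle_rho[2]))
  cbind(ls[, 1] + la[, 1],   # slow  x directed
        ls[, 2] + la[, 1],   # fast  x directed
        ls[, 1] + la[, 2],   # slow  x tortuous
        ls[, 2] + la[, 2])   # fast  x tortuous
}

new_mixture_params <- function(speed_shape, speed_rate, angle_rho, weights,
                               degenerate = FALSE, loglik = NA_real_) {
  structure(list(speed_shape = speed_shape, speed_rate = speed_rate,
                 angle_rho = angle_rho, weights = weights,
                 degenerate = degenerate, loglik = loglik),
            class = "mixture_params")
}

# weighted gamma MLE via Newton on the shape equation log(k)-digamma(k)=s
fit_gamma_weighted <- function(x, w) {
  x <- pmax(x, 1e-6)
  w <- w / sum(w)
  mu <- sum(w * x)
  s <- log(mu) - sum(w * log(x))
  s <- max(s, 1e-8)
  k <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in 1:25) {
    g <- log(k) - digamma(k) - s
    k_new <- k - g / (1 / k - trigamma(k))
    if (!is.finite(k_new) || k_new <= 0) break
    if (abs(k_new - k) < 1e-10 * k) { k <- k_new; break }
    k <- k_new
  }
  c(shape = k, rate = k / mu)
}

# weighted wrapped-Cauchy concentration MLE (mean fixed at 0)
fit_wc_weighted <- function(theta, w) {
  w <- w / sum(w)
  f <- function(rho) -sum(w * dwrapped_cauchy_log(theta, rho))
  stats::optimize(f, c(0, 0.9999))$minimum
}

#' Fit the 4-component movement mixture by EM
#'
#' Maximum-likelihood fit of the gamma-by-wrapped-Cauchy product mixture over
#' valid steps, with seeded random restarts. The EM log-likelihood is
#' non-decreasing at every iteration; components are relabelled afterwards so
#' the fast speed component has the larger mean and the directed angle
#' component the larger concentration. A fit is flagged degenerate when any
#' mixture weight falls below 1e-3 (callers may fall back to fewer modes).
#'
#' @param steps a \code{step_series}.
#' @param n_restarts number of seeded random restarts (best likelihood kept).
#' @param seed integer seed making the restarts reproducible.
#' @param max_iter,tol EM stopping rule: relative log-likelihood change below
#'   \code{tol} or \code{max_iter} iterations.
#' @return a \code{mixture_params}: gamma (shape, rate) per speed component,
#'   wrapped-Cauchy concentration per angle component, 4 mixture weights, the
#'   final log-likelihood, and a degeneracy flag.
#' @export
fit_movement_mixture <- function(steps, n_restarts = 20, seed = 1L,
                                 max_iter = 500, tol = 1e-8) {
  ok <- steps$valid & !is.na(steps$turn_rad) & is.finite(steps$speed_kmh)
  v <- pmax(steps$speed_kmh[ok], 1e-6)
  th <- steps$turn_rad[ok]
  n <- length(v)
  if (n < 30) stop("need at least 30 valid steps")
  if (stats::sd(v) < 1e-8 || stats::sd(th) < 1e-8) {
    # no variation to separate components: flag immediately
    g <- fit_gamma_weighted(v, rep(1, n))
    rho <- fit_wc_weighted(th, rep(1, n))
    return(new_mixture_params(rep(g[1], 2), rep(g[2], 2), c(rho, rho),
                              rep(0.25, 4), degenerate = TRUE))
  }
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    qs <- stats::quantile(v, c(0.25, 0.75))
    mu_s <- qs[1] * stats::runif(1, 0.7, 1.3)
    mu_f <- qs[2] * stats::runif(1, 0.7, 1.3)
    par <- list(speed_shape = c(2, 2),
                speed_rate = c(2 / mu_s, 2 / mu_f),
                # directed component starts concentrated, tortuous diffuse
                angle_rho = c(stats::runif(1, 0.55, 0.95),
                              stats::runif(1, 0.02, 0.45)),
                weights = rep(0.25, 4))
    ll_trace <- numeric(0)
    ll_prev <- -Inf
    for (it in seq_len(max_iter)) {
      lc <- component_loglik(v, th, par)
      lw <- sweep(lc, 2, log(pmax(par$weights, 1e-300)), "+")
      mx <- apply(lw, 1, max)
      ll <- sum(mx + log(rowSums(exp(lw - mx))))
      ll_trace <- c(ll_trace, ll)
      resp <- exp(lw - mx - log(rowSums(exp(lw - mx))))
      # M-step
      w_new <- colMeans(resp)
      w_slow <- resp[, 1] + resp[, 3]; w_fast <- resp[, 2] + resp[, 4]
      w_dir <- resp[, 1] + resp[, 2]; w_tor <- resp[, 3] + resp[, 4]
      if (sum(w_slow) > 1e-8) {
        g1 <- fit_gamma_weighted(v, w_slow)
      } else g1 <- c(par$speed_shape[1], par$speed_rate[1])
      if (sum(w_fast) > 1e-8) {
        g2 <- fit_gamma_weighted(v, w_fast)
      } else g2 <- c(par$speed_shape[2], par$speed_rate[2])
      r1 <- if (sum(w_dir) > 1e-8) fit_wc_weighted(th, w_dir) else par$angle_rho[1]
      r2 <- if (sum(w_tor) > 1e-8) fit_wc_weighted(th, w_tor) else par$angle_rho[2]
      par <- list(speed_shape = c(g1[1], g2[1]),
                  speed_rate = c(g1[2], g2[2]),
                  angle_rho = c(r1, r2), weights = w_new)
      if (is.finite(ll_prev) && abs(ll - ll_prev) < tol * abs(ll_prev)) break
      ll_prev <- ll
    }
    if (is.null(best) || ll > best$ll)
      best <- list(par = par, ll = ll, trace = ll_trace)
  }
  par <- best$par
  # relabel: fast speed component has larger mean; directed rho is larger
  means <- par$speed_shape / par$speed_rate
  if (means[1] > means[2]) {
    par$speed_shape <- rev(par$speed_shape)
    par$speed_rate <- rev(par$speed_rate)
    par$weights <- par$weights[c(2, 1, 4, 3)]
  }
  if (par$angle_rho[1] < par$angle_rho[2]) {
    par$angle_rho <- rev(par$angle_rho)
    par$weights <- par$weights[c(3, 4, 1, 2)]
  }
  out <- new_mixture_params(unname(par$speed_shape), unname(par$speed_rate),
                            unname(par$angle_rho), unname(par$weights),
                            degenerate = any(par$weights < 1e-3),
                            loglik = best$ll)
  attr(out, "ll_trace") <- best$trace
  out
}

#' Classify steps into behavioural modes
#'
#' Each valid step is assigned the mode whose component likelihood (speed
#' times turning angle, equal priors -- the mixture weights are used only in
#' fitting) is largest; exact ties break towards transit (the lower mode
#' number). With \code{window_steps > 1} the assignment maximizes the summed
#' component log-likelihood of the trajectory segment centred on the step
#' (the likelihood of the segment belonging to each mode), which suppresses
#' single-step noise at the cost of blurring mode boundaries by up to half a
#' window. Invalid steps are left unassigned (NA) and carried as gaps.
#'
#' @param steps a \code{step_series}.
#' @param params a \code{mixture_params}.
#' @param window_steps odd segment length in steps (default 1 = single-step
#'   classification).
#' @return a \code{mode_sequence}: data.frame with \code{t0, t1, mode}
#'   (integer 1-4 or NA), \code{error_dominated} (advisory flag, mode 4), and
#'   the four per-step component log-likelihoods \code{ll1..ll4}.
#' @export
classify_steps <- function(steps, params, window_steps = 1) {
  stopifnot(window_steps >= 1, window_steps %% 2 == 1)
  n <- nrow(steps)
  mode <- rep(NA_integer_, n)
  ll <- matrix(NA_real_, n, 4)
  ok <- steps$valid & !is.na(steps$turn_rad) & is.finite(steps$speed_kmh)
  if (any(ok)) {
    lc <- matrix(NA_real_, n, 4)
    lc[ok, ] <- component_loglik(pmax(steps$speed_kmh[ok], 1e-6),
                                 steps$turn_rad[ok], params)
    half <- (window_steps - 1) / 2
    for (i in which(ok)) {
      ix <- max(1, i - half):min(n, i + half)
      sl <- colSums(lc[ix, , drop = FALSE], na.rm = TRUE)
      mode[i] <- which.max(sl)  # which.max: first max = lower mode
    }
    ll[ok, ] <- lc[ok, ]
  }
  out <- data.frame(animal_id = steps$animal_id,
                    t0 = steps$t0, t1 = steps$t1,
                    mode = mode,
                    error_dominated = !is.na(mode) & mode == 4L)
  out$ll1 <- ll[, 1]; out$ll2 <- ll[, 2]; out$ll3 <- ll[, 3]; out$ll4 <- ll[, 4]
  class(out) <- c("mode_sequence", "data.frame")
  out
}

# run-length smoothing of an integer vector with NAs treated as hard breaks
smooth_runs_int <- function(m, min_run) {
  if (min_run <= 1 || length(m) < 2) return(m)
  segs <- split(seq_along(m), cumsum(c(TRUE, diff(is.na(m)) != 0)))
  for (s in segs) {
    if (anyNA(m[s]) || length(s) < 2) next
    v <- m[s]
    repeat {
      r <- rle(v)
      if (length(r$lengths) <= 1) break
      short <- which(r$lengths < min_run)
      if (!length(short)) break
      j <- short[which.min(r$lengths[short])]
      left_len <- if (j > 1) r$lengths[j - 1] else -1L
      right_len <- if (j < length(r$lengths)) r$lengths[j + 1] else -1L
      r$values[j] <- if (left_len >= right_len) r$values[j - 1] else r$values[j + 1]
      v <- inverse.rle(r)
    }
    m[s] <- v
  }
  m
}

#' Absorb short mode runs into their neighbours
#'
#' Runs shorter than \code{min_run_steps} are merged into the flanking run
#' with the greater length (ties towards the earlier run), shortest offending
#' run first, until none remain; the result is a fixed point (smoothing twice
#' equals smoothing once). \code{min_run_steps = 1} is the identity.
#' Unclassified (NA) steps act as segment boundaries.
#'
#' @param modes a \code{mode_sequence}.
#' @param min_run_steps minimum run length to keep (>= 1); the default 2 steps
#'   = 1 day suppresses single-step flicker.
#' @return the \code{mode_sequence} with smoothed modes (the advisory flag is
#'   recomputed).
#' @export
smooth_modes <- function(modes, min_run_steps = 2) {
  stopifnot(min_run_steps >= 1)
  m <- smooth_runs_int(modes$mode, min_run_steps)
  modes$mode <- m
  modes$error_dominated <- !is.na(m) & m == 4L
  modes
}

#' Bout statistics for area-restricted behaviour
#'
#' Modes 3 and 4 are merged as ARB. Bout durations are run lengths times the
#' step length; inter-ARB intervals are measured between consecutive bouts
#' within each animal's sequence.
#'
#' @param modes a \code{mode_sequence} (single animal).
#' @param step_days step duration in days (default 0.5).
#' @return list with \code{bout_days}, \code{interval_days},
#'   \code{n_modes_seen} (distinct modes classified).
#' @export
bout_statistics <- function(modes, step_days = 0.5) {
  m <- modes$mode
  arb <- !is.na(m) & m %in% c(3L, 4L)
  r <- rle(arb)
  bouts <- r$lengths[r$values] * step_days
  # intervals between consecutive ARB bouts: non-ARB runs strictly between
  iv <- numeric(0)
  if (sum(r$values) >= 2) {
    pos <- which(r$values)
    for (k in seq_len(length(pos) - 1)) {
      between <- (pos[k] + 1):(pos[k + 1] - 1)
      iv <- c(iv, sum(r$lengths[between]) * step_days)
    }
  }
  list(bout_days = bouts, interval_days = iv,
       n_modes_seen = length(unique(stats::na.omit(m))))
}
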