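# Synthetic tag-data generator. Movement is a mode-switching discrete-step
# process at (default) 1-h resolution -- deliberately NOT a CTCRW -- so that
# recovery tests exercise the analysis chain against a mechanistically
# different truth. Defaults target the study conditions: slow/fast transit
# speeds 0.74 and 1.93 km/h, ARB bouts averaging 5.5 days, inter-ARB
# intervals averaging ~14.3 days, ~2.3 locations/day with multi-day gaps,
# heavy-tailed geolocation errors with latitude error >> longitude error, and
# 12-bin depth summaries at 3/6/12-h periods.

MODE_NAMES <- c("slow-transit", "fast-transit", "slow-ARB", "fast-ARB")

default_mode_rates <- function() {
  # off-diagonal switch rates per day; rows = from, cols = to
  Q <- matrix(0, 4, 4, dimnames = list(MODE_NAMES, MODE_NAMES))
  Q[1, ] <- c(0, 0.15, 0.065, 0.005)   # transit -> ARB total 0.07/day (~14.3 d)
  Q[2, ] <- c(0.15, 0, 0.065, 0.005)
  Q[3, ] <- c(0.09, 0.09, 0, 0)        # ARB exit ~0.18/day (~5.5 d bouts)
  Q[4, ] <- c(0.10, 0.10, 0, 0)
  Q
}

#' Simulation configuration
#'
#' @param mode_rates 4x4 matrix of continuous-time switch rates (per day,
#'   off-diagonal, non-negative); modes are 1 slow-transit, 2 fast-transit,
#'   3 slow-ARB, 4 fast-ARB.
#' @param speed_mean,speed_sd per-mode step-speed mean/SD in km/h (truncated
#'   normal, lower bound 0).
#' @param turn_rho per-mode wrapped-Cauchy concentration (in [0, 1)) of the
#'   per-internal-step heading increment; transit modes concentrated near 0,
#'   ARB modes diffuse.
#' @param release lon/lat of the release position (degrees).
#' @param release_time release datetime (POSIXct, UTC); anchors day/night.
#' @param duration_days track length in days.
#' @param obs_rate_per_day Poisson rate of Argos observations.
#' @param gap_schedule list of \code{c(start_day, length_days)} intervals with
#'   no observations.
#' @param class_freq named Argos class frequencies (classes 3,2,1,0,A,B).
#' @param internal_step_h internal simulation step (hours).
#' @param initial_mode starting mode (1-4).
#' @param arb_suppress_days force transit modes for this many days after
#'   release (capture-effect experiments).
#' @param depth_bin_edges upper edges (m) of the 12 depth summary bins.
#' @param summary_period_h depth summary period: 3, 6 or 12 hours.
#' @param transit_depth_mean,transit_depth_sd,arb_depth_mean,arb_depth_sd
#'   mode-conditioned period maximum-depth distribution (m).
#' @param day_surface_frac,night_surface_frac target fraction of time within
#'   the surface bin by day and by night.
#' @param seed integer seed; every draw is reproducible given it.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(mode_rates = default_mode_rates(),
                       speed_mean = c(0.74, 1.93, 0.74, 1.93),
                       speed_sd = c(0.56, 1.04, 0.56, 1.04),
                       turn_rho = c(0.97, 0.97, 0.3, 0.3),
                       release = c(lon = 176, lat = -37),
                       release_time = as.POSIXct("2006-02-01 00:00:00", tz = "UTC"),
                       duration_days = 60,
                       obs_rate_per_day = 2.3,
                       gap_schedule = list(),
                       class_freq = c("3" = 0.05, "2" = 0.10, "1" = 0.15,
                                      "0" = 0.20, "A" = 0.25, "B" = 0.25),
                       internal_step_h = 1,
                       initial_mode = 2L,
                       arb_suppress_days = 0,
                       depth_bin_edges = c(1, 5, 10, 25, 50, 75, 100,
                                           150, 200, 250, 300, 1000),
                       summary_period_h = 6,
                       transit_depth_mean = 127, transit_depth_sd = 57,
                       arb_depth_mean = 108, arb_depth_sd = 49,
                       day_surface_frac = 0.514, night_surface_frac = 0.640,
                       seed = 1L) {
  stopifnot(is.matrix(mode_rates), dim(mode_rates) == c(4, 4),
            all(mode_rates[row(mode_rates) != col(mode_rates)] >= 0),
            all(speed_mean >= 0), all(speed_sd >= 0),
            all(turn_rho >= 0 & turn_rho < 1),
            duration_days > 0, obs_rate_per_day >= 0,
            summary_period_h %in% c(3, 6, 12),
            length(depth_bin_edges) == 12,
            !is.unsorted(depth_bin_edges, strictly = TRUE),
            all(depth_bin_edges > 0),
            initial_mode %in% 1:4, arb_suppress_days >= 0)
  if (abs(sum(class_freq) - 1) > 1e-9) stop("class_freq must sum to 1")
  structure(as.list(environment()), class = "sim_config")
}

# Wrapped-Cauchy draws with mean 0 and concentration rho.
rwrapped_cauchy <- function(n, rho) {
  if (rho >= 1) return(rep(0, n))
  u <- stats::runif(n)
  wrap_angle(2 * atan(((1 - rho) / (1 + rho)) * tan(pi * (u - 0.5))))
}

# Truncated-normal (lower bound 0) draws by rejection with a final clamp.
rtnorm0 <- function(n, mean, sd) {
  if (all(sd == 0)) return(pmax(mean, 0))
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:20) {
    bad <- x < 0
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean[bad], sd[bad])
  }
  pmax(x, 0)
}

#' Simulate the behavioural mode sequence
#'
#' Realizes the continuous-time Markov chain given by \code{cfg$mode_rates}
#' (Gillespie algorithm) and samples it onto the internal time grid. With
#' \code{arb_suppress_days > 0}, transitions into the ARB modes (3, 4) are
#' disabled before that time.
#'
#' @param cfg a [sim_config()].
#' @param seed overrides \code{cfg$seed}.
#' @return list with \code{times} (days, internal grid), \code{mode} (integer
#'   1-4 per grid step) and \code{sojourns} (data.frame of start, end, mode).
#' @export
simulate_modes <- function(cfg, seed = cfg$seed) {
  set.seed(seed)
  Q <- cfg$mode_rates; diag(Q) <- 0
  if (all(Q == 0) && is.null(cfg$initial_mode))
    stop("all switch rates zero and no initial mode")
  t <- 0; m <- as.integer(cfg$initial_mode)
  if (cfg$arb_suppress_days > 0 && m %in% c(3L, 4L)) m <- 2L
  st <- numeric(0); sm <- integer(0); se <- numeric(0)
  seg_start <- 0
  while (t < cfg$duration_days) {
    rates <- Q[m, ]
    if (t < cfg$arb_suppress_days) rates[c(3, 4)] <- 0
    tot <- sum(rates)
    if (tot <= 0) {
      # no exit possible now; jump to end of suppression window or finish
      t_next <- if (t < cfg$arb_suppress_days && sum(Q[m, ]) > 0)
        cfg$arb_suppress_days else cfg$duration_days
      t <- t_next
      if (t >= cfg$duration_days) break
      next
    }
    dt <- stats::rexp(1, tot)
    if (t < cfg$arb_suppress_days && t + dt > cfg$arb_suppress_days) {
      # censor the waiting time at the suppression boundary and redraw there
      t <- cfg$arb_suppress_days
      next
    }
    t <- t + dt
    if (t >= cfg$duration_days) break
    st <- c(st, seg_start); sm <- c(sm, m); se <- c(se, t)
    m <- sample.int(4, 1, prob = rates)
    seg_start <- t
  }
  st <- c(st, seg_start); sm <- c(sm, m); se <- c(se, cfg$duration_days)
  step_d <- cfg$internal_step_h / 24
  times <- seq(0, cfg$duration_days - step_d / 2, by = step_d)
  mode <- sm[findInterval(times, st)]
  list(times = times, mode = as.integer(mode),
       sojourns = data.frame(start = st, end = se, mode = sm))
}

#' Simulate a movement path from a mode sequence
#'
#' Each internal step draws a speed (truncated normal, lower bound 0) and a
#' heading increment (wrapped Cauchy, mean 0) from the current mode's
#' parameters and advances the position along the great circle.
#'
#' @param modes result of [simulate_modes()].
#' @param cfg a [sim_config()].
#' @param seed overrides \code{cfg$seed} (offset internally so the path draw
#'   is independent of the mode draw).
#' @return a \code{true_path}: data.frame with \code{t} (days), \code{lon},
#'   \code{lat}, \code{mode}, \code{speed_kmh}, \code{heading_rad}.
#' @export
simulate_path <- function(modes, cfg, seed = cfg$seed) {
  set.seed(seed + 1000L)
  n <- length(modes$times)
  m <- modes$mode
  sp <- rtnorm0(n, cfg$speed_mean[m], cfg$speed_sd[m])
  dturn <- numeric(n)
  for (k in 1:4) {
    ix <- which(m == k)
    if (length(ix)) dturn[ix] <- rwrapped_cauchy(length(ix), cfg$turn_rho[k])
  }
  heading <- wrap_angle(stats::runif(1, -pi, pi) + cumsum(dturn))
  lon <- numeric(n + 1); lat <- numeric(n + 1)
  lon[1] <- wrap_lon360(cfg$release[[1]]); lat[1] <- cfg$release[[2]]
  dist <- sp * cfg$internal_step_h
  for (i in seq_len(n)) {
    p <- destination_point(lon[i], lat[i], heading[i], dist[i])
    lon[i + 1] <- p$lon; lat[i + 1] <- p$lat
  }
  out <- data.frame(t = c(modes$times, cfg$duration_days),
                    lon = lon, lat = lat,
                    mode = c(m, m[n]),
                    speed_kmh = c(sp, sp[n]),
                    heading_rad = c(heading, heading[n]))
  class(out) <- c("true_path", "data.frame")
  out
}

# Interpolate a true path at arbitrary times (unwrapped longitude so
# antimeridian crossings interpolate correctly).
interp_path <- function(path, times) {
  ulon <- path$lon
  d <- diff(ulon)
  d <- d - 360 * round(d / 360)
  ulon <- ulon[1] + c(0, cumsum(d))
  lon <- stats::approx(path$t, ulon, xout = times, rule = 2)$y
  lat <- stats::approx(path$t, path$lat, xout = times, rule = 2)$y
  data.frame(t = times, lon = wrap_lon360(lon), lat = lat)
}

in_gap <- function(t, gap_schedule) {
  if (!length(gap_schedule)) return(rep(FALSE, length(t)))
  res <- rep(FALSE, length(t))
  for (g in gap_schedule) res <- res | (t >= g[1] & t < g[1] + g[2])
  res
}

# km -> degrees at a given latitude
km_to_deg_lon <- function(km, lat) km / (EARTH_RADIUS_KM * pi / 180 * cos(.deg2rad(lat)))
km_to_deg_lat <- function(km) km / (EARTH_RADIUS_KM * pi / 180)

#' Simulate Argos observations of a path
#'
#' Observation times follow a Poisson process at \code{cfg$obs_rate_per_day},
#' thinned by the gap schedule; each observation gets a quality class drawn
#' from \code{cfg$class_freq} and Gaussian lon/lat errors with the class's
#' error-model SD.
#'
#' @param path a \code{true_path}.
#' @param cfg a [sim_config()].
#' @param err an [error_model()].
#' @param seed overrides \code{cfg$seed}.
#' @param animal_id identifier for the output rows.
#' @return an \code{observation_set}.
#' @export
observe_argos <- function(path, cfg, err, seed = cfg$seed, animal_id = "sim") {
  set.seed(seed + 2000L)
  lambda <- cfg$obs_rate_per_day * cfg$duration_days
  n <- stats::rpois(1, lambda)
  t <- sort(stats::runif(n, 0, cfg$duration_days))
  t <- t[!in_gap(t, cfg$gap_schedule)]
  cls <- sample(names(cfg$class_freq), length(t), replace = TRUE,
                prob = cfg$class_freq)
  pos <- interp_path(path, t)
  sds <- obs_error_sd(err, cls)
  lon <- pos$lon + km_to_deg_lon(stats::rnorm(length(t), 0, sds$sd_lon_km), pos$lat)
  lat <- pos$lat + km_to_deg_lat(stats::rnorm(length(t), 0, sds$sd_lat_km))
  new_observation_set(data.frame(animal_id = rep(animal_id, length(t)), t = t,
                                 lon = wrap_lon360(lon),
                                 lat = pmin(pmax(lat, -90), 90),
                                 loc_class = cls,
                                 stringsAsFactors = FALSE))
}

#' Simulate light-geolocation observations of a path
#'
#' One observation per day at the local-noon-equivalent time (solar noon at
#' the release longitude), with errors drawn from a scaled t distribution
#' (\code{df = err$gl_t_df}); the latitude scale exceeds the longitude scale,
#' reproducing the characteristic heavy-tailed geolocation error structure.
#'
#' @inheritParams observe_argos
#' @return an \code{observation_set} with class \code{GL} rows.
#' @export
observe_geolocation <- function(path, cfg, err, seed = cfg$seed,
                                animal_id = "sim") {
  set.seed(seed + 3000L)
  noon_frac <- ((12 - wrap_lon360(cfg$release[[1]]) / 15) %% 24) / 24
  t <- seq(0, floor(cfg$duration_days) - 1) + noon_frac
  t <- t[t <= cfg$duration_days & !in_gap(t, cfg$gap_schedule)]
  pos <- interp_path(path, t)
  e_lon <- stats::rt(length(t), df = err$gl_t_df) * err$gl_sd_lon_km
  e_lat <- stats::rt(length(t), df = err$gl_t_df) * err$gl_sd_lat_km
  lon <- pos$lon + km_to_deg_lon(e_lon, pos$lat)
  lat <- pos$lat + km_to_deg_lat(e_lat)
  new_observation_set(data.frame(animal_id = rep(animal_id, length(t)), t = t,
                                 lon = wrap_lon360(lon),
                                 lat = pmin(pmax(lat, -90), 90),
                                 loc_class = "GL",
                                 stringsAsFactors = FALSE))
}

#' Simulate binned time-at-depth summaries
#'
#' Emits one 12-bin summary per \code{cfg$summary_period_h}-hour period in the
#' pop-up-archival-tag format. Each period's maximum depth is drawn from the
#' mode-conditioned distribution (transit deeper than ARB), the surface-bin
#' fraction targets the configured day/night values (day < night), and the
#' remaining time decays smoothly with depth down to the period maximum.
#'
#' @param modes result of [simulate_modes()].
#' @param cfg a [sim_config()].
#' @param seed overrides \code{cfg$seed}.
#' @param animal_id identifier.
#' @return a \code{depth_summaries} list: \code{edges} (12 upper bin edges,
#'   metres; lower edge of bin 1 is 0), and \code{data} with one row per
#'   period: \code{animal_id, period_start, period_hours, daylight, mode,
#'   max_depth_m, p1..p12}.
#' @export
simulate_depth <- function(modes, cfg, seed = cfg$seed, animal_id = "sim") {
  set.seed(seed + 4000L)
  edges <- cfg$depth_bin_edges
  if (is.unsorted(edges, strictly = TRUE)) stop("bin edges must be strictly increasing")
  period_d <- cfg$summary_period_h / 24
  starts <- seq(0, cfg$duration_days - period_d + 1e-9, by = period_d)
  nP <- length(starts)
  lower <- c(0, edges[-12])
  mids <- (lower + edges) / 2
  P <- matrix(0, nP, 12)
  maxd <- numeric(nP)
  daylight <- logical(nP)
  dommode <- integer(nP)
  for (i in seq_len(nP)) {
    mid_t <- starts[i] + period_d / 2
    when <- cfg$release_time + mid_t * 86400
    daylight[i] <- day_night_flag(when, cfg$release[[1]], cfg$release[[2]]) == "day"
    ix <- which(modes$times >= starts[i] & modes$times < starts[i] + period_d)
    mm <- if (length(ix)) modes$mode[ix] else modes$mode[length(modes$mode)]
    tab <- tabulate(mm, 4)
    dommode[i] <- which.max(tab)  # ties -> lower mode (transit)
    arb <- dommode[i] %in% c(3L, 4L)
    mu <- if (arb) cfg$arb_depth_mean else cfg$transit_depth_mean
    sdd <- if (arb) cfg$arb_depth_sd else cfg$transit_depth_sd
    maxd[i] <- max(rtnorm0(1, mu, sdd), 5)
    target <- if (daylight[i]) cfg$day_surface_frac else cfg$night_surface_frac
    # beta noise around the surface-time target, concentration 50
    ps <- if (target >= 1 - 1e-12) 1 else if (target <= 1e-12) 0 else
      stats::rbeta(1, target * 50, (1 - target) * 50)
    reach <- lower < maxd[i]
    reach[1] <- TRUE
    w <- exp(-mids / pmax(maxd[i] / 2, 1)) * reach
    w[1] <- 0
    p <- numeric(12)
    p[1] <- ps
    if (sum(w) > 0) p <- p + (1 - ps) * w / sum(w) else p[1] <- 1
    P[i, ] <- p / sum(p)
  }
  colnames(P) <- paste0("p", 1:12)
  structure(list(edges = edges,
                 data = cbind(data.frame(animal_id = animal_id,
                                         period_start = starts,
                                         period_hours = cfg$summary_period_h,
                                         daylight = ifelse(daylight, "day", "night"),
                                         mode = dommode,
                                         max_depth_m = maxd,
                                         stringsAsFactors = FALSE),
                              as.data.frame(P))),
            class = "depth_summaries")
}

#' Simulate a complete synthetic deployment
#'
#' Driver chaining [simulate_modes()], [simulate_path()], [observe_argos()],
#' [observe_geolocation()] and [simulate_depth()].
#'
#' @param cfg a [sim_config()].
#' @param animal_id identifier.
#' @param geolocation include light-geolocation (class GL) observations.
#' @param err an [error_model()].
#' @return list with \code{truth} (true path), \code{modes}, \code{obs}
#'   (combined observation set) and \code{depth}.
#' @export
simulate_track <- function(cfg, animal_id = "sim", geolocation = TRUE,
                           err = error_model()) {
  modes <- simulate_modes(cfg)
  path <- simulate_path(modes, cfg)
  path$animal_id <- animal_id
  oa <- observe_argos(path, cfg, err, animal_id = animal_id)
  obs <- if (geolocation) {
    og <- observe_geolocation(path, cfg, err, animal_id = animal_id)
    new_observation_set(rbind(oa, og))
  } else oa
  # collapse near-coincident times from the two streams
  keep <- c(TRUE, diff(obs$t) > 1e-6)
  obs <- new_observation_set(obs[keep, , drop = FALSE])
  depth <- simulate_depth(modes, cfg, animal_id = animal_id)
  list(truth = path, modes = modes, obs = obs, depth = depth)
}
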