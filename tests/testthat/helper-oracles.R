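# Independent oracles used across the suite. Each is written from first
# principles (dense linear algebra, exhaustive enumeration, hand lifetables)
# and never calls the implementation path it checks.

# Dense joint-Gaussian log-density of a 1-D CTCRW observation sequence:
# builds the full covariance of the observed positions by propagating state
# covariances (no Kalman recursion) and evaluates the multivariate normal
# log-density directly.
dense_ctcrw_loglik_1d <- function(t, y, sd, beta, sigma, v0_var = 1e6) {
  n <- length(t)
  p <- ctcrw_params(beta, sigma)
  V <- vector("list", n)
  Phis <- vector("list", n)
  V[[1]] <- diag(c(sd[1]^2, v0_var))
  if (n > 1) for (i in 2:n) {
    m <- ctcrw_matrices(p, t[i] - t[i - 1])
    Phis[[i]] <- m$Phi
    V[[i]] <- m$Phi %*% V[[i - 1]] %*% t(m$Phi) + m$Q
  }
  C <- matrix(0, n, n)
  for (j in 1:n) {
    A <- diag(2)
    for (i in j:n) {
      if (i > j) A <- Phis[[i]] %*% A
      C[i, j] <- (A %*% V[[j]])[1, 1]
      C[j, i] <- C[i, j]
    }
  }
  S <- C + diag(sd^2, n)
  L <- chol(S)
  z <- backsolve(L, y - y[1], transpose = TRUE)
  -0.5 * n * log(2 * pi) - sum(log(diag(L))) - 0.5 * sum(z^2)
}

# Build an observation_set from planar km coordinates around a centre.
obs_from_planar <- function(t, x, y, loc_class, center = c(190, -30),
                            animal_id = "a") {
  ll <- unproject_aeqd(x, y, center[1], center[2])
  df <- data.frame(animal_id = animal_id, t = t, lon = ll$lon, lat = ll$lat,
                   loc_class = loc_class, stringsAsFactors = FALSE)
  class(df) <- c("observation_set", "data.frame")
  df
}

# Exhaustive two-sided Wilcoxon rank-sum p-value by enumerating every
# assignment of the pooled ranks to the first sample (no ties assumed).
exact_ranksum_p <- function(x, y) {
  n <- length(x); m <- length(y)
  r <- rank(c(x, y))
  W_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(n + m, n)
  Ws <- apply(combs, 2, function(ix) sum(seq_len(n + m)[ix]) - n * (n + 1) / 2)
  mu <- n * m / 2
  mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-9)
}

# Hand product-limit lifetable: S(t) at each distinct event time.
hand_km <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  S <- 1
  out <- data.frame(time = ut, surv = NA_real_)
  for (k in seq_along(ut)) {
    at_risk <- sum(time >= ut[k])
    d <- sum(time == ut[k] & event == 1)
    S <- S * (1 - d / at_risk)
    out$surv[k] <- S
  }
  out
}

# Low-precision Astronomical Almanac solar elevation (independent of the
# package's Spencer-series formulation): different derivation of declination
# and equation of time via the solar mean anomaly and ecliptic longitude.
almanac_solar_elevation <- function(time, lon, lat) {
  time <- as.POSIXct(time, tz = "UTC")
  # days since J2000.0
  d <- as.numeric(difftime(time, as.POSIXct("2000-01-01 12:00:00", tz = "UTC"),
                           units = "days"))
  g <- (357.529 + 0.98560028 * d) %% 360          # mean anomaly, deg
  q <- (280.459 + 0.98564736 * d) %% 360          # mean longitude, deg
  L <- (q + 1.915 * sin(g * pi / 180) + 0.020 * sin(2 * g * pi / 180)) %% 360
  e <- 23.439 - 0.00000036 * d                    # obliquity, deg
  ra <- atan2(cos(e * pi / 180) * sin(L * pi / 180), cos(L * pi / 180))
  decl <- asin(sin(e * pi / 180) * sin(L * pi / 180))
  # Greenwich mean sidereal time, hours
  gmst <- (18.697374558 + 24.06570982441908 * d) %% 24
  lon180 <- ((lon + 180) %% 360) - 180
  lst <- (gmst + lon180 / 15) %% 24
  ha <- (lst * 15 - ra * 180 / pi) * pi / 180
  latr <- lat * pi / 180
  el <- asin(sin(latr) * sin(decl) + cos(latr) * cos(decl) * cos(ha))
  el * 180 / pi
}
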