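# Day/night time-at-depth aggregation of pop-up archival tag summaries,
# gap interpolation, and the mode-conditioned maximum-depth contrast.

#' Solar elevation angle
#'
#' Geometric solar elevation (degrees, no refraction) at a UTC time and
#' position, from the NOAA fractional-year formulation (Spencer series for
#' declination and equation of time). Accuracy is well under half a degree,
#' a few minutes of timing error at the study's mid latitudes.
#'
#' @param time POSIXct (UTC).
#' @param lon,lat position in degrees (either longitude convention).
#' @return elevation in degrees.
#' @export
solar_elevation <- function(time, lon, lat) {
  time <- as.POSIXlt(time, tz = "UTC")
  doy <- time$yday
  hour <- time$hour + time$min / 60 + time$sec / 3600
  g <- 2 * pi / 365 * (doy + (hour - 12) / 24)  # fractional year, radians
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  lon180 <- ((lon + 180) %% 360) - 180
  tst <- hour * 60 + eqtime + 4 * lon180         # true solar time, minutes
  ha <- .deg2rad(tst / 4 - 180)                  # hour angle
  latr <- .deg2rad(lat)
  sinel <- sin(latr) * sin(decl) + cos(latr) * cos(decl) * cos(ha)
  .rad2deg(asin(pmin(pmax(sinel, -1), 1)))
}

#' Day/night flag
#'
#' "day" iff the geometric solar elevation is above the horizon at the given
#' UTC time and position.
#'
#' @inheritParams solar_elevation
#' @return character vector, "day" or "night".
#' @export
day_night_flag <- function(time, lon, lat) {
  ifelse(solar_elevation(time, lon, lat) > 0, "day", "night")
}

# map fine bins (lower_i, upper_i] onto common bins by exact containment;
# returns the common-bin index per fine bin or stops if a bin straddles.
map_bins <- function(fine_upper, common_upper, label = "summary") {
  fine_lower <- c(0, fine_upper[-length(fine_upper)])
  common_lower <- c(0, common_upper[-length(common_upper)])
  idx <- integer(length(fine_upper))
  for (j in seq_along(fine_upper)) {
    hit <- which(common_lower <= fine_lower[j] + 1e-9 &
                   fine_upper[j] <= common_upper + 1e-9)
    if (!length(hit))
      stop("bin (", fine_lower[j], ", ", fine_upper[j], "] of ", label,
           " straddles a common-bin edge")
    idx[j] <- hit[1]
  }
  idx
}

#' Aggregate time-at-depth over summaries
#'
#' Maps each tag's 12 summary bins onto a common bin set (by exact edge
#' containment; a bin straddling a common edge is an error naming the
#' summary), then averages the proportions per day/night flag weighted by
#' period length, renormalizing to 1.
#'
#' @param summaries a \code{depth_summaries} object or list of them (one per
#'   tag, possibly with different bin edges).
#' @param common_bins increasing upper edges (m) of the common bins (lower
#'   edge of the first bin is 0).
#' @return matrix with rows "day"/"night" (those present) and one column per
#'   common bin.
#' @export
aggregate_tad <- function(summaries, common_bins = c(1, 10, 50, 100, 200, 300, Inf)) {
  if (inherits(summaries, "depth_summaries")) summaries <- list(summaries)
  stopifnot(!is.unsorted(common_bins, strictly = TRUE))
  nb <- length(common_bins)
  acc <- list(day = rep(0, nb), night = rep(0, nb))
  wt <- c(day = 0, night = 0)
  for (s in summaries) {
    idx <- map_bins(s$edges, common_bins,
                    label = paste0("tag ", s$data$animal_id[1]))
    P <- as.matrix(s$data[, paste0("p", 1:12)])
    coarse <- matrix(0, nrow(P), nb)
    for (j in seq_len(12)) coarse[, idx[j]] <- coarse[, idx[j]] + P[, j]
    w <- s$data$period_hours
    for (fl in c("day", "night")) {
      sel <- s$data$daylight == fl
      if (any(sel)) {
        acc[[fl]] <- acc[[fl]] + colSums(coarse[sel, , drop = FALSE] * w[sel])
        wt[fl] <- wt[fl] + sum(w[sel])
      }
    }
  }
  keep <- names(wt)[wt > 0]
  out <- do.call(rbind, lapply(keep, function(fl) acc[[fl]] / sum(acc[[fl]])))
  rownames(out) <- keep
  colnames(out) <- paste0("<=", common_bins, "m")
  out
}

# tricube-weighted local-linear fit at x0 from observed (x, y)
local_linear_at <- function(x0, x, y, bandwidth) {
  d <- abs(x - x0)
  h <- max(bandwidth, sort(d)[min(2, length(d))] + 1e-9)  # >= 2 points in window
  w <- (1 - pmin(d / h, 1)^3)^3
  use <- w > 0
  if (sum(use) < 2) {
    use <- order(d)[1:2]
    w[use] <- 1e-6
    use <- seq_along(x) %in% use
  }
  fit <- stats::lm.wfit(cbind(1, x[use] - x0), y[use], w[use])
  unname(fit$coefficients[1])
}

#' Interpolate gaps in a binned depth time series
#'
#' Fills missing summary periods per bin by tricube-weighted local-linear
#' smoothing over period index, clamps to non-negative, and renormalizes each
#' filled period across bins to the simplex. A bin observed in fewer than 2
#' periods is left empty and flagged.
#'
#' @param series numeric matrix, periods x bins; rows with NA are gaps.
#' @param bandwidth smoothing half-window in periods (default 5).
#' @return list with \code{filled} (matrix) and \code{empty_bins} (indices
#'   never observed).
#' @export
interpolate_gaps <- function(series, bandwidth = 5) {
  series <- as.matrix(series)
  filled <- series
  empty <- integer(0)
  pid <- seq_len(nrow(series))
  for (j in seq_len(ncol(series))) {
    obs <- which(!is.na(series[, j]))
    if (length(obs) < 2) { empty <- c(empty, j); next }
    mis <- which(is.na(series[, j]))
    for (i in mis)
      filled[i, j] <- local_linear_at(i, pid[obs], series[obs, j], bandwidth)
  }
  filled <- pmax(filled, 0)
  was_gap <- apply(is.na(series), 1, any)
  for (i in which(was_gap)) {
    s <- sum(filled[i, ], na.rm = TRUE)
    if (is.finite(s) && s > 0) filled[i, ] <- filled[i, ] / s
  }
  list(filled = filled, empty_bins = empty)
}

#' Maximum-depth contrast between transit and ARB periods
#'
#' Assigns each summary period the behavioural mode covering the majority of
#' the period (ties towards transit), groups periods into transit (modes 1-2)
#' and ARB (modes 3-4), and applies the rank-sum contrast to the period
#' maximum depths (transit minus ARB).
#'
#' @param period_max_depths numeric vector of per-period maximum depths (m).
#' @param period_modes integer vector (1-4) of the mode assigned to each
#'   period, aligned with \code{period_max_depths}.
#' @param exclude_mode4 drop error-dominated (fast-ARB) periods.
#' @return a \code{period_contrast} (see [rank_sum_contrast()]).
#' @export
max_depth_by_mode <- function(period_max_depths, period_modes,
                              exclude_mode4 = FALSE) {
  stopifnot(length(period_max_depths) == length(period_modes))
  ok <- !is.na(period_modes) & is.finite(period_max_depths)
  if (exclude_mode4) ok <- ok & period_modes != 4L
  transit <- period_max_depths[ok & period_modes %in% c(1L, 2L)]
  arb <- period_max_depths[ok & period_modes %in% c(3L, 4L)]
  if (length(transit) < 2 || length(arb) < 2)
    stop("need at least 2 periods in each of the transit and ARB groups")
  rank_sum_contrast(transit, arb)
}

#' Assign behavioural modes to summary periods
#'
#' Majority-overlap alignment of a classified 12-h mode sequence onto depth
#' summary periods; ties break towards transit (the lower mode).
#'
#' @param period_start,period_hours period windows (days since release,
#'   hours).
#' @param modes a \code{mode_sequence}.
#' @return integer vector of modes (NA where no classified step overlaps).
#' @export
align_modes_to_periods <- function(period_start, period_hours, modes) {
  vapply(seq_along(period_start), function(i) {
    a <- period_start[i]; b <- a + period_hours[i] / 24
    ov <- pmin(modes$t1, b) - pmax(modes$t0, a)
    ov[ov < 0] <- 0
    ok <- ov > 0 & !is.na(modes$mode)
    if (!any(ok)) return(NA_integer_)
    w <- tapply(ov[ok], modes$mode[ok], sum)
    as.integer(names(w)[which.max(w)])  # ties -> first = lower mode
  }, integer(1))
}
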