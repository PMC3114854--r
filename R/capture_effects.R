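# Post-release capture-effect analyses: time to first area-restricted
# behaviour (Kaplan-Meier), early-vs-late movement contrasts, heading
# alignment, and seasonal return-to-capture classification.

#' Time to first ARB per animal
#'
#' Event = start time of the first step classified as ARB (modes 3 or 4);
#' animals with no ARB step are right-censored at the end of their last
#' classified step. Empty or wholly unclassified sequences are excluded with
#' a warning.
#'
#' @param sequences list of \code{mode_sequence} objects (one per animal).
#' @return data.frame with columns \code{animal_id, time, event} (1 = first
#'   ARB observed, 0 = censored).
#' @export
first_arb_times <- function(sequences) {
  rows <- lapply(sequences, function(ms) {
    cl <- which(!is.na(ms$mode))
    if (!nrow(ms) || !length(cl)) return(NULL)
    arb <- which(!is.na(ms$mode) & ms$mode %in% c(3L, 4L))
    if (length(arb)) {
      data.frame(animal_id = ms$animal_id[1], time = ms$t0[arb[1]], event = 1L)
    } else {
      data.frame(animal_id = ms$animal_id[1], time = ms$t1[cl[length(cl)]],
                 event = 0L)
    }
  })
  dropped <- sum(vapply(rows, is.null, logical(1)))
  if (dropped) warning(dropped, " empty sequence(s) excluded")
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no usable sequences")
  rownames(out) <- NULL
  out
}

#' Kaplan-Meier curve with Greenwood variance
#'
#' Product-limit estimate of S(t) = P(no ARB by t) with Greenwood variance
#' and pointwise log-log 95% confidence limits (clipped to [0, 1]).
#' Estimation goes through \code{survival::survfit}; the Greenwood variance is
#' recomputed from the at-risk/event counts for the returned curve object.
#'
#' @param events data.frame with columns \code{time} (>= 0) and \code{event}
#'   (1 = event, 0 = censored), as from [first_arb_times()].
#' @return a \code{km_curve}: data.frame with \code{time, n_risk, n_event,
#'   surv, greenwood_var, lower, upper}.
#' @export
km_estimator <- function(events) {
  if (!nrow(events)) stop("no event rows")
  if (any(events$time < 0)) stop("negative event times")
  sf <- survival::survfit(survival::Surv(events$time, events$event) ~ 1,
                          conf.type = "log-log", conf.int = 0.95)
  d <- sf$n.event; n <- sf$n.risk; S <- sf$surv
  gw <- S^2 * cumsum(ifelse(n > d, d / (n * (n - d)), 0))
  out <- data.frame(time = sf$time, n_risk = n, n_event = d, surv = S,
                    greenwood_var = gw,
                    lower = pmin(pmax(ifelse(is.na(sf$lower), 0, sf$lower), 0), 1),
                    upper = pmin(pmax(ifelse(is.na(sf$upper), 1, sf$upper), 0), 1))
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Median crossing time of a survival curve
#'
#' Smallest event time at which the survival estimate falls to 0.5 or below
#' (the day at which the odds of having shown ARB are even); \code{NA} if the
#' curve never reaches 0.5.
#'
#' @param curve a \code{km_curve}.
#' @return time in days, or \code{NA_real_}.
#' @export
median_crossing <- function(curve) {
  ix <- which(curve$surv <= 0.5 + 1e-12)
  if (!length(ix)) return(NA_real_)
  curve$time[ix[1]]
}

#' Rank-sum contrast between two samples
#'
#' Two-sided Wilcoxon rank-sum test (exact null distribution for small
#' untied samples, normal approximation with tie correction otherwise, as in
#' \code{stats::wilcox.test}) plus the Hodges-Lehmann location-shift estimate
#' (median of pairwise differences x - y). If every value in both samples is
#' identical the contrast is defined as p = 1, shift = 0.
#'
#' @param x,y numeric samples (each >= 2 values).
#' @return a \code{period_contrast}: list with \code{stat_x, stat_y} (sample
#'   medians), \code{W} (rank-sum statistic), \code{p} (two-sided),
#'   \code{hl_shift}.
#' @export
rank_sum_contrast <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2 || length(y) < 2) stop("both samples need >= 2 values")
  if (length(unique(c(x, y))) == 1) {
    out <- list(stat_x = stats::median(x), stat_y = stats::median(y),
                W = length(x) * length(y) / 2, p = 1, hl_shift = 0)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, conf.int = TRUE))
    hl <- unname(wt$estimate)
    out <- list(stat_x = stats::median(x), stat_y = stats::median(y),
                W = unname(wt$statistic), p = min(unname(wt$p.value), 1),
                hl_shift = hl)
  }
  class(out) <- "period_contrast"
  out
}

#' Early-vs-late speed contrast
#'
#' Pools step speeds across animals, splits them at \code{split_days} after
#' release, and applies the rank-sum contrast (early minus late).
#'
#' @param steps a \code{step_series} (possibly row-bound across animals) with
#'   \code{t0} in days since release.
#' @param split_days boundary between the early and late windows (default the
#'   10-day post-release window).
#' @return a \code{period_contrast}.
#' @export
early_late_speed <- function(steps, split_days = 10) {
  ok <- steps$valid & is.finite(steps$speed_kmh)
  early <- steps$speed_kmh[ok & steps$t0 < split_days]
  late <- steps$speed_kmh[ok & steps$t0 >= split_days]
  if (length(early) < 2 || length(late) < 2)
    stop("empty early or late window at split_days = ", split_days)
  rank_sum_contrast(early, late)
}

#' Northward heading alignment
#'
#' Mean northward component (cosine of the bearing from north; +1 = due
#' north, 0 = due east/west) of step headings inside a post-release window,
#' with a one-sample t test against 0.
#'
#' @param steps a \code{step_series}.
#' @param window_days use steps with \code{t0 < window_days}; \code{Inf} for
#'   all steps.
#' @return list with \code{mean_north}, \code{t}, \code{p}, \code{n}.
#' @export
heading_alignment <- function(steps, window_days = 10) {
  ok <- steps$valid & is.finite(steps$heading_rad) & steps$t0 < window_days
  h <- steps$heading_rad[ok]
  if (length(h) < 5) stop("need at least 5 headings in the window")
  comp <- cos(h)
  if (stats::sd(comp) < 1e-12) {
    # degenerate: every heading identical; the test statistic is undefined
    return(list(mean_north = mean(comp), t = NA_real_, p = NA_real_,
                n = length(comp)))
  }
  tt <- stats::t.test(comp, mu = 0)
  list(mean_north = mean(comp), t = unname(tt$statistic),
       p = unname(tt$p.value), n = length(comp))
}

#' Departure/return classification relative to the capture location
#'
#' An animal "departs" when its distance from the release point first exceeds
#' \code{departure_km}; it "returns" if, after departing, the distance later
#' falls below \code{radius_km}. Releases dated strictly before the season
#' split (default 1 March) are "early season".
#'
#' @param track a \code{regular_track} (or data.frame with \code{lon, lat}).
#' @param release c(lon, lat) of the capture/release position.
#' @param release_date release \code{Date} (or NA: season flag NA).
#' @param radius_km return radius (default 500 km).
#' @param departure_km distance that must be exceeded before a return can be
#'   scored (default 100 km).
#' @param season_split "MM-DD" split (default "03-01").
#' @return list with logicals \code{departed}, \code{returned},
#'   \code{early_season}, and \code{max_dist_km}, \code{final_dist_km}.
#' @export
return_classifier <- function(track, release, release_date = NA,
                              radius_km = 500, departure_km = 100,
                              season_split = "03-01") {
  d <- haversine_km(track$lon, track$lat, release[[1]], release[[2]])
  dep_ix <- which(d > departure_km)[1]
  departed <- !is.na(dep_ix)
  returned <- departed && any(d[dep_ix:length(d)] < radius_km)
  early <- NA
  if (!is.na(release_date)) {
    release_date <- as.Date(release_date)
    split_date <- as.Date(paste0(format(release_date, "%Y"), "-", season_split))
    early <- release_date < split_date
  }
  list(departed = departed, returned = returned, early_season = early,
       max_dist_km = max(d), final_dist_km = d[length(d)])
}
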