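# Shared experiment builders for recovery tests.

# Well-separated component configuration: step-level speed means 0.7 vs 1.9
# km/h and turning concentrations 0.8 vs 0.1, multi-day sojourns with roughly
# balanced occupancy, and frequent high-quality (class 3) Argos coverage.
separated_sim_config <- function(seed, duration_days = 150,
                                 obs_rate_per_day = 6) {
  Q <- matrix(0, 4, 4)
  Q[1, ] <- c(0, 0.2, 0.14, 0.01) / 3
  Q[2, ] <- c(0.2, 0, 0.14, 0.01) / 3
  Q[3, ] <- c(0.09, 0.09, 0, 0) / 3
  Q[4, ] <- c(0.1, 0.1, 0, 0) / 3
  sim_config(seed = seed, duration_days = duration_days, internal_step_h = 12,
             mode_rates = Q,
             turn_rho = c(0.8, 0.8, 0.1, 0.1),
             speed_mean = c(0.7, 1.9, 0.7, 1.9),
             speed_sd = c(0.25, 0.45, 0.25, 0.45),
             obs_rate_per_day = obs_rate_per_day,
             class_freq = c("3" = 1, "2" = 0, "1" = 0,
                            "0" = 0, "A" = 0, "B" = 0))
}

# True (majority) mode per 12-h step of a step_series, from the generator's
# internal mode grid.
true_mode_per_step <- function(steps, modes) {
  vapply(seq_len(nrow(steps)), function(i) {
    ix <- which(modes$times >= steps$t0[i] - 1e-9 &
                  modes$times < steps$t1[i] - 1e-9)
    m <- modes$mode[ix]
    if (!length(m)) return(NA_integer_)
    as.integer(names(which.max(table(m))))
  }, integer(1))
}

# One end-to-end replicate: simulate -> fit CTCRW -> smooth to 12 h ->
# step metrics -> fit mixture -> segment-window classify -> run smoothing.
# Returns the fraction of steps whose mode matches the generator truth.
mode_recovery_replicate <- function(seed, err = error_model()) {
  cfg <- separated_sim_config(seed)
  s <- simulate_track(cfg, geolocation = FALSE, err = err)
  f <- fit_ctcrw(s$obs, err)
  tr <- smooth_predict(s$obs, f$params, err)
  st <- step_metrics(tr)
  mp <- fit_movement_mixture(st, n_restarts = 20, seed = seed)
  ms <- smooth_modes(classify_steps(st, mp, window_steps = 5), 2)
  truth <- true_mode_per_step(st, s$modes)
  ok <- !is.na(ms$mode) & !is.na(truth)
  mean(ms$mode[ok] == truth[ok])
}
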