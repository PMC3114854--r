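# End-to-end pipeline driver: simulate -> regularize -> classify ->
# capture-effects -> depth, with per-stage CSV/JSON artifacts and a run
# manifest. Every stochastic stage draws its seed deterministically from the
# single root seed.

.pipeline_keys <- c("seed", "out_dir", "n_animals", "sim", "error_model",
                    "stages", "step_hours", "min_run", "restarts",
                    "split_days", "radius_km", "departure_km", "common_bins",
                    "gap_threshold_days", "geolocation")

#' Build and validate a pipeline configuration
#'
#' @param config list or path to a YAML file. Recognised keys: \code{seed}
#'   (integer root seed; required, no wall-clock seeding), \code{out_dir},
#'   \code{n_animals}, \code{sim} (overrides passed to [sim_config()]),
#'   \code{error_model} (overrides passed to [error_model()]), \code{stages}
#'   (subset of simulate, regularize, classify, capture_effects, depth),
#'   \code{step_hours}, \code{min_run}, \code{restarts}, \code{split_days},
#'   \code{radius_km}, \code{departure_km}, \code{common_bins},
#'   \code{gap_threshold_days}, \code{geolocation}. Unknown keys are rejected
#'   before any stage runs.
#' @return a validated \code{pipeline_config} list with defaults filled in.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), .pipeline_keys)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$seed)) stop("config must set an explicit seed")
  defaults <- list(out_dir = tempfile("mtrack_run_"), n_animals = 5L,
                   sim = list(), error_model = list(),
                   stages = c("simulate", "regularize", "classify",
                              "capture_effects", "depth"),
                   step_hours = 12, min_run = 2L, restarts = 20L,
                   split_days = 10, radius_km = 500, departure_km = 100,
                   common_bins = c(1, 10, 50, 100, 200, 300, Inf),
                   gap_threshold_days = 20, geolocation = TRUE)
  cfg <- utils::modifyList(defaults, config)
  cfg$seed <- as.integer(cfg$seed)
  bad <- setdiff(cfg$stages, c("simulate", "regularize", "classify",
                               "capture_effects", "depth"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Deterministic given the config and its seed. Writes per-stage artifacts
#' under \code{cfg$out_dir}: \code{locations.csv}, \code{truth.csv},
#' \code{tracks.csv}, \code{modes.csv}, \code{depth_summaries.csv},
#' \code{report.json} and \code{manifest.json}.
#'
#' @param cfg a [pipeline_config()] (or list/path coercible to one).
#' @return invisibly, the report list (also serialized to report.json).
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) cfg <- pipeline_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  err <- do.call(error_model, cfg$error_model)
  stages <- cfg$stages
  report <- list(seed = cfg$seed, n_animals = cfg$n_animals, stages = stages)

  sims <- NULL
  if ("simulate" %in% stages) {
    sims <- lapply(seq_len(cfg$n_animals), function(i) {
      sc <- do.call(sim_config, utils::modifyList(cfg$sim,
                                                  list(seed = cfg$seed + 17L * i)))
      simulate_track(sc, animal_id = sprintf("SIM%02d", i),
                     geolocation = cfg$geolocation, err = err)
    })
    all_obs <- do.call(rbind, lapply(sims, `[[`, "obs"))
    write_locations(all_obs, file.path(cfg$out_dir, "locations.csv"))
    truth <- do.call(rbind, lapply(sims, function(s)
      s$truth[, c("animal_id", "t", "lon", "lat", "mode")]))
    utils::write.csv(truth, file.path(cfg$out_dir, "truth.csv"), row.names = FALSE)
    dd_all <- do.call(rbind, lapply(sims, function(s) s$depth$data))
    utils::write.csv(dd_all, file.path(cfg$out_dir, "depth_summaries.csv"),
                     row.names = FALSE)
  }

  tracks <- NULL; fits <- NULL
  if ("regularize" %in% stages) {
    if (is.null(sims)) stop("regularize stage requires the simulate stage (no external input wired)")
    fits <- lapply(sims, function(s)
      fit_ctcrw(s$obs, err, init = ctcrw_params(1, 20)))
    tracks <- Map(function(s, f) {
      smooth_predict(s$obs, f$params, err,
                     grid = regular_grid(s$obs, cfg$step_hours / 24),
                     gap_threshold_days = cfg$gap_threshold_days)
    }, sims, fits)
    tr <- do.call(rbind, lapply(tracks, as.data.frame))
    utils::write.csv(tr, file.path(cfg$out_dir, "tracks.csv"), row.names = FALSE)
    report$ctcrw <- lapply(fits, function(f)
      list(beta = f$params$beta, sigma = f$params$sigma,
           loglik = f$loglik, converged = f$converged))
  }

  steps_all <- NULL; mode_seqs <- NULL
  if ("classify" %in% stages) {
    if (is.null(tracks)) stop("classify stage requires the regularize stage")
    steps_all <- lapply(tracks, step_metrics)
    mode_seqs <- Map(function(st, i) {
      mp <- fit_movement_mixture(st, n_restarts = cfg$restarts,
                                 seed = cfg$seed + 31L * i)
      smooth_modes(classify_steps(st, mp), cfg$min_run)
    }, steps_all, seq_along(steps_all))
    md <- do.call(rbind, lapply(mode_seqs, function(m)
      m[, c("animal_id", "t0", "t1", "mode", "error_dominated")]))
    utils::write.csv(md, file.path(cfg$out_dir, "modes.csv"), row.names = FALSE)
    bouts <- lapply(mode_seqs, bout_statistics, step_days = cfg$step_hours / 24)
    report$behaviour <- list(
      mean_bout_days = mean(unlist(lapply(bouts, `[[`, "bout_days"))),
      mean_interval_days = mean(unlist(lapply(bouts, `[[`, "interval_days"))),
      modes_per_individual = vapply(bouts, `[[`, numeric(1), "n_modes_seen"))
  }

  if ("capture_effects" %in% stages) {
    if (is.null(mode_seqs)) stop("capture_effects stage requires the classify stage")
    ev <- first_arb_times(mode_seqs)
    km <- km_estimator(ev)
    pooled <- do.call(rbind, steps_all)
    contrast <- tryCatch(early_late_speed(pooled, cfg$split_days),
                         error = function(e) NULL)
    heads <- tryCatch(heading_alignment(pooled, cfg$split_days),
                      error = function(e) NULL)
    returns <- Map(function(tr, s) {
      rc <- return_classifier(tr, c(tr$lon[1], tr$lat[1]),
                              release_date = as.Date(s$truth$t[1],
                                                     origin = as.Date("2006-02-01")),
                              radius_km = cfg$radius_km,
                              departure_km = cfg$departure_km)
      rc[c("departed", "returned", "early_season")]
    }, tracks, sims)
    report$capture_effects <- list(
      km = as.data.frame(km), crossing_day = median_crossing(km),
      early_late_speed = if (!is.null(contrast)) unclass(contrast) else NULL,
      heading = heads, returns = returns)
  }

  if ("depth" %in% stages) {
    if (is.null(sims)) stop("depth stage requires the simulate stage")
    dsum <- lapply(sims, `[[`, "depth")
    dd <- do.call(rbind, lapply(dsum, `[[`, "data"))
    tad <- aggregate_tad(dsum, cfg$common_bins)
    depth_contrast <- NULL
    if (!is.null(mode_seqs)) {
      pm <- unlist(Map(function(s, m)
        align_modes_to_periods(s$depth$data$period_start,
                               s$depth$data$period_hours, m), sims, mode_seqs))
      depth_contrast <- tryCatch(
        unclass(max_depth_by_mode(dd$max_depth_m, pm)), error = function(e) NULL)
    }
    report$depth <- list(tad = tad, contrast = depth_contrast,
                         day_surface = unname(tad["day", 1]),
                         night_surface = unname(tad["night", 1]))
  }

  manifest <- list(package_version = as.character(utils::packageVersion("marlintrack")),
                   seed = cfg$seed, stages = stages,
                   config_hash = sum(utf8ToInt(paste(deparse(unclass(cfg)),
                                                     collapse = ""))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}

#' Assemble a human-readable run report
#'
#' Reads the artifacts written by [run_pipeline()] and produces a markdown
#' summary plus the parsed report list; numbers round-trip from the stage
#' outputs without recomputation. Missing artifacts are listed and the report
#' covers the stages that are present.
#'
#' @param out_dir pipeline output directory.
#' @param include_table1 append the packaged deployment-table summary.
#' @return list with \code{report} (parsed JSON), \code{missing} (artifact
#'   names) and \code{markdown} (character vector of lines).
#' @export
make_report <- function(out_dir, include_table1 = TRUE) {
  want <- c("locations.csv", "tracks.csv", "modes.csv",
            "depth_summaries.csv", "report.json")
  missing <- want[!file.exists(file.path(out_dir, want))]
  rep_path <- file.path(out_dir, "report.json")
  report <- if (file.exists(rep_path)) jsonlite::read_json(rep_path,
                                                           simplifyVector = TRUE)
            else list()
  md <- c("# Pipeline run report", "")
  if (length(missing)) md <- c(md, paste("Missing artifacts:",
                                         paste(missing, collapse = ", ")), "")
  if (!is.null(report$behaviour))
    md <- c(md, sprintf("- Mean ARB bout duration: %.2f days",
                        report$behaviour$mean_bout_days),
            sprintf("- Modes per individual: %s",
                    paste(report$behaviour$modes_per_individual, collapse = ", ")))
  if (length(report$capture_effects$crossing_day) &&
      is.finite(report$capture_effects$crossing_day))
    md <- c(md, sprintf("- KM 50:50 crossing: day %.1f",
                        report$capture_effects$crossing_day))
  if (!is.null(report$depth))
    md <- c(md, sprintf("- Surface time day/night: %.3f / %.3f",
                        report$depth$day_surface, report$depth$night_surface))
  if (include_table1) {
    ds <- summarize_deployments(read_table1_fixture())
    md <- c(md, "", "## Deployment table",
            sprintf("- %d animals, mean weight %.1f kg", ds$n_animals,
                    ds$mean_weight_kg),
            sprintf("- Totals: %d days at liberty, %d SLRT days, %d PSAT days",
                    ds$total_days_at_liberty, ds$total_slrt_days,
                    ds$total_psat_days))
    report$table1 <- ds
  }
  list(report = report, missing = missing, markdown = md)
}
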