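# Domain types and I/O for location observations and the packaged deployment
# table.

ARGOS_CLASSES <- c("3", "2", "1", "0", "A", "B", "GL")

#' Location-class error model
#'
#' Measurement-error scales for Argos quality classes 3, 2, 1, 0, A, B and for
#' light/SST geolocations (class \code{GL}). Per-class SD (km) is
#' \code{base_sd * multiplier}; GL errors have their own, much larger scales
#' with latitude error exceeding longitude error, and heavy (t-distributed)
#' tails in simulation.
#'
#' @param base_sd_lon_km,base_sd_lat_km reference (class 3) SD in km.
#' @param k_mult named numeric multipliers for classes "3","2","1","0","A","B";
#'   must be non-decreasing from class 3 to class B.
#' @param gl_sd_lon_km,gl_sd_lat_km geolocation error scales in km; the
#'   latitude scale must be at least the longitude scale.
#' @param gl_t_df degrees of freedom (> 0) of the t-distributed geolocation
#'   errors used by the simulator.
#' @return an object of class \code{error_model}.
#' @export
error_model <- function(base_sd_lon_km = 0.5, base_sd_lat_km = 0.5,
                        k_mult = c("3" = 1, "2" = 1.5, "1" = 3,
                                   "0" = 6, "A" = 12, "B" = 24),
                        gl_sd_lon_km = 56.8, gl_sd_lat_km = 112.2,
                        gl_t_df = 3) {
  stopifnot(base_sd_lon_km >= 0, base_sd_lat_km >= 0, gl_t_df > 0,
            all(k_mult > 0), gl_sd_lon_km >= 0, gl_sd_lat_km >= 0)
  k_mult <- k_mult[c("3", "2", "1", "0", "A", "B")]
  if (anyNA(k_mult)) stop("k_mult must name all classes 3,2,1,0,A,B")
  if (is.unsorted(k_mult)) stop("class multipliers must be non-decreasing from 3 to B")
  if (gl_sd_lat_km < gl_sd_lon_km) stop("GL latitude scale must be >= longitude scale")
  structure(list(base_sd_lon_km = base_sd_lon_km,
                 base_sd_lat_km = base_sd_lat_km,
                 k_mult = k_mult,
                 gl_sd_lon_km = gl_sd_lon_km, gl_sd_lat_km = gl_sd_lat_km,
                 gl_t_df = gl_t_df),
            class = "error_model")
}

#' Per-observation measurement SDs in km
#'
#' @param err an [error_model()].
#' @param loc_class character vector of class labels.
#' @param error_scale free multiplier applied to every class SD.
#' @return data.frame with columns `sd_lon_km`, `sd_lat_km`.
#' @export
obs_error_sd <- function(err, loc_class, error_scale = 1) {
  stopifnot(inherits(err, "error_model"), error_scale >= 0)
  bad <- !loc_class %in% ARGOS_CLASSES
  if (any(bad)) stop("unknown location class: ", paste(unique(loc_class[bad]), collapse = ", "))
  gl <- loc_class == "GL"
  m <- err$k_mult[loc_class]
  sd_lon <- ifelse(gl, err$gl_sd_lon_km, err$base_sd_lon_km * m)
  sd_lat <- ifelse(gl, err$gl_sd_lat_km, err$base_sd_lat_km * m)
  data.frame(sd_lon_km = unname(sd_lon) * error_scale,
             sd_lat_km = unname(sd_lat) * error_scale)
}

new_observation_set <- function(df) {
  stopifnot(all(c("animal_id", "t", "lon", "lat", "loc_class") %in% names(df)))
  df <- df[order(df$animal_id, df$t), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("observation_set", "data.frame")
  df
}

#' Read location observations
#'
#' Reads delimited text with columns \code{animal_id, timestamp, lon, lat,
#' loc_class}. Timestamps are either ISO-8601 datetimes (converted to decimal
#' days since each animal's first observation, assumed UTC) or already-numeric
#' decimal days since release. Longitudes are normalized to [0, 360). Rows
#' with an unknown class label are dropped with a warning; latitudes outside
#' [-90, 90] are a hard error naming the row. Duplicate timestamps within an
#' animal keep the better Argos class (3 > 2 > 1 > 0 > A > B > GL) and the
#' discard is reported via a warning.
#'
#' @param path file path.
#' @param delim field delimiter (default comma).
#' @return an \code{observation_set}: a data.frame with columns
#'   \code{animal_id, t, lon, lat, loc_class}, sorted by animal and time.
#' @export
read_locations <- function(path, delim = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE)
  need <- c("animal_id", "timestamp", "lon", "lat", "loc_class")
  if (!all(need %in% names(raw)))
    stop("location file must have columns: ", paste(need, collapse = ", "))
  raw$loc_class <- as.character(raw$loc_class)
  bad_lat <- which(abs(raw$lat) > 90)
  if (length(bad_lat))
    stop("latitude out of range at row(s): ", paste(bad_lat, collapse = ", "))
  bad_cls <- which(!raw$loc_class %in% ARGOS_CLASSES)
  if (length(bad_cls)) {
    warning("dropping ", length(bad_cls), " row(s) with unknown location class: ",
            paste(unique(raw$loc_class[bad_cls]), collapse = ", "))
    raw <- raw[-bad_cls, , drop = FALSE]
  }
  if (is.numeric(raw$timestamp)) {
    t <- as.numeric(raw$timestamp)
  } else {
    ts <- as.POSIXct(raw$timestamp, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                    "%Y-%m-%d"))
    if (anyNA(ts)) stop("unparseable timestamp at row(s): ",
                        paste(which(is.na(ts)), collapse = ", "))
    t0 <- stats::ave(as.numeric(ts), raw$animal_id, FUN = min)
    t <- (as.numeric(ts) - t0) / 86400
  }
  df <- data.frame(animal_id = as.character(raw$animal_id), t = t,
                   lon = wrap_lon360(raw$lon), lat = raw$lat,
                   loc_class = raw$loc_class, stringsAsFactors = FALSE)
  df <- df[order(df$animal_id, df$t,
                 match(df$loc_class, ARGOS_CLASSES)), , drop = FALSE]
  dup <- duplicated(df[, c("animal_id", "t")])
  if (any(dup)) {
    warning("collapsed ", sum(dup),
            " duplicate timestamp(s); kept the better location class")
    df <- df[!dup, , drop = FALSE]
  }
  new_observation_set(df)
}

#' Write location observations
#'
#' Canonical-dialect inverse of [read_locations()]: times are written as
#' decimal days since release, so a write/read round trip preserves every
#' retained field.
#'
#' @param obs an \code{observation_set}.
#' @param path output file path.
#' @param delim field delimiter.
#' @export
write_locations <- function(obs, path, delim = ",") {
  out <- data.frame(animal_id = obs$animal_id,
                    timestamp = obs$t,
                    lon = obs$lon, lat = obs$lat,
                    loc_class = obs$loc_class)
  utils::write.table(out, path, sep = delim, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a track as a GeoJSON LineString
#'
#' One LineString per animal, coordinates in [-180, 180] as GeoJSON requires.
#'
#' @param track data.frame with \code{animal_id, t, lon, lat}.
#' @param path output file path.
#' @export
write_track_geojson <- function(track, path) {
  feats <- lapply(split(track, track$animal_id), function(tr) {
    lon180 <- ((tr$lon + 180) %% 360) - 180
    list(type = "Feature",
         properties = list(animal_id = tr$animal_id[1],
                           t_start = min(tr$t), t_end = max(tr$t)),
         geometry = list(type = "LineString",
                         coordinates = Map(c, lon180, tr$lat)))
  })
  jsonlite::write_json(list(type = "FeatureCollection",
                            features = unname(feats)),
                       path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}

#' Packaged deployment-summary table
#'
#' Returns the 25-row deployment table shipped with the package: one row per
#' tagged striped marlin (IDs STM05.2 to STM08.2) with weight, start date,
#' start/end positions, days at liberty, SLRT and PSAT data days, and the
#' longest observation gap. Rows flagged \code{no_transmit} or
#' \code{slrt_only} have zero PSAT days.
#'
#' @return data.frame of 25 rows, one per deployment.
#' @export
read_table1_fixture <- function() {
  path <- system.file("extdata", "table1_deployments.csv",
                      package = "marlintrack", mustWork = FALSE)
  if (!nzchar(path) || !file.exists(path))
    stop("packaged deployment table not found; reinstall the package")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("marlin_id", "weight_kg", "start_date", "start_lat", "start_lon",
            "end_lat", "end_lon", "days_at_liberty", "slrt_days",
            "psat_days", "max_gap_days", "note")
  if (!identical(names(df), need) || nrow(df) != 25L)
    stop("packaged deployment table is corrupt")
  df$start_date <- as.Date(df$start_date)
  df$end_lon <- wrap_lon360(df$end_lon)
  df$start_lon <- wrap_lon360(df$start_lon)
  df
}

#' Summarize a deployment table
#'
#' Arithmetic means and column totals across deployments, counts by tagging
#' year, and the double-tagged vs SLRT-only split (a deployment with zero PSAT
#' data days counts as SLRT-only).
#'
#' @param rows data.frame in the layout of [read_table1_fixture()].
#' @return list with \code{n_animals}, \code{mean_weight_kg},
#'   \code{mean_days_at_liberty}, \code{mean_slrt_days}, \code{mean_psat_days},
#'   \code{mean_max_gap_days}, \code{total_days_at_liberty},
#'   \code{total_slrt_days}, \code{total_psat_days}, \code{years} (named
#'   counts), \code{n_double_tagged}, \code{n_slrt_only}.
#' @export
summarize_deployments <- function(rows) {
  if (NROW(rows) == 0) stop("no deployment rows")
  yr <- format(as.Date(rows$start_date), "%Y")
  list(n_animals = nrow(rows),
       mean_weight_kg = mean(rows$weight_kg),
       mean_days_at_liberty = mean(rows$days_at_liberty),
       mean_slrt_days = mean(rows$slrt_days),
       mean_psat_days = mean(rows$psat_days),
       mean_max_gap_days = mean(rows$max_gap_days),
       total_days_at_liberty = sum(rows$days_at_liberty),
       total_slrt_days = sum(rows$slrt_days),
       total_psat_days = sum(rows$psat_days),
       years = table(yr),
       n_double_tagged = sum(rows$psat_days > 0),
       n_slrt_only = sum(rows$psat_days == 0))
}
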