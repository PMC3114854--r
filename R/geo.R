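# Spherical geodesy shared by every stage. All distances use a sphere of
# radius 6371 km; geolocation error (tens of km) dwarfs the ellipsoidal
# correction, so spherical formulas are used throughout.

EARTH_RADIUS_KM <- 6371.0

#' Normalize longitudes to [0, 360)
#'
#' The study region spans the antimeridian, so longitudes are stored in the
#' [0, 360) convention internally; tracks crossing 180 degrees stay
#' monotone-representable. Inputs in either [-180, 180) or [0, 360) are
#' accepted.
#'
#' @param lon numeric vector of longitudes in degrees.
#' @return longitudes in [0, 360).
#' @export
wrap_lon360 <- function(lon) {
  lon %% 360
}

#' Wrap an angle to (-pi, pi]
#'
#' Exact reversals map to +pi, the declared convention for turning angles.
#'
#' @param theta numeric vector of angles in radians.
#' @return angles in (-pi, pi].
#' @export
wrap_angle <- function(theta) {
  r <- theta %% (2 * pi)
  ifelse(r > pi, r - 2 * pi, r)
}

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km. Vectorised over
#' coordinates; either longitude convention is accepted.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees.
#' @return distance(s) in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  p1 <- .deg2rad(lat1); p2 <- .deg2rad(lat2)
  dlat <- p2 - p1
  dlon <- .deg2rad((lon2 - lon1 + 180) %% 360 - 180)
  a <- sin(dlat / 2)^2 + cos(p1) * cos(p2) * sin(dlon / 2)^2
  a <- pmin(a, 1)
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Initial great-circle bearing
#'
#' Bearing from north, radians in (-pi, pi], of the great circle from point 1
#' towards point 2. 0 = due north, pi/2 = due east.
#'
#' @param lon1,lat1,lon2,lat2 coordinates in degrees.
#' @return bearing(s) in radians.
#' @export
bearing_rad <- function(lon1, lat1, lon2, lat2) {
  p1 <- .deg2rad(lat1); p2 <- .deg2rad(lat2)
  dlon <- .deg2rad((lon2 - lon1 + 180) %% 360 - 180)
  y <- sin(dlon) * cos(p2)
  x <- cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dlon)
  atan2(y, x)
}

# Destination point given start, bearing (rad from north) and distance (km).
# Used by the movement simulator to advance positions on the sphere.
destination_point <- function(lon, lat, bearing, dist_km) {
  d <- dist_km / EARTH_RADIUS_KM
  p1 <- .deg2rad(lat)
  l1 <- .deg2rad(lon)
  p2 <- asin(sin(p1) * cos(d) + cos(p1) * sin(d) * cos(bearing))
  l2 <- l1 + atan2(sin(bearing) * sin(d) * cos(p1),
                   cos(d) - sin(p1) * sin(p2))
  list(lon = wrap_lon360(.rad2deg(l2)), lat = .rad2deg(p2))
}

#' Project to a local azimuthal-equidistant tangent plane
#'
#' Projects lon/lat (degrees) to planar x/y kilometres centred on
#' (`lon0`, `lat0`). Distances from the centre are exact; the CTCRW filter is
#' linear-Gaussian in these planar coordinates. Centre the projection on each
#' animal's own track so distortion stays bounded over the ~40 degrees of
#' longitude a track can span.
#'
#' @param lon,lat coordinates in degrees.
#' @param lon0,lat0 projection centre in degrees.
#' @return list with `x`, `y` in km.
#' @export
project_aeqd <- function(lon, lat, lon0, lat0) {
  p <- .deg2rad(lat); p0 <- .deg2rad(lat0)
  dl <- .deg2rad((lon - lon0 + 180) %% 360 - 180)
  cosc <- sin(p0) * sin(p) + cos(p0) * cos(p) * cos(dl)
  cosc <- pmin(pmax(cosc, -1), 1)
  c_ang <- acos(cosc)
  k <- ifelse(c_ang < 1e-12, 1, c_ang / sin(c_ang))
  x <- EARTH_RADIUS_KM * k * cos(p) * sin(dl)
  y <- EARTH_RADIUS_KM * k * (cos(p0) * sin(p) - sin(p0) * cos(p) * cos(dl))
  list(x = x, y = y)
}

#' Inverse azimuthal-equidistant projection
#'
#' @param x,y planar coordinates in km.
#' @param lon0,lat0 projection centre in degrees.
#' @return list with `lon` (in [0, 360)) and `lat` in degrees.
#' @export
unproject_aeqd <- function(x, y, lon0, lat0) {
  p0 <- .deg2rad(lat0)
  rho <- sqrt(x^2 + y^2)
  c_ang <- rho / EARTH_RADIUS_KM
  near0 <- rho < 1e-9
  sinc <- sin(c_ang); cosc <- cos(c_ang)
  lat <- ifelse(near0, lat0,
                .rad2deg(asin(pmin(pmax(cosc * sin(p0) + y * sinc * cos(p0) / pmax(rho, 1e-300), -1), 1))))
  lon <- ifelse(near0, lon0,
                lon0 + .rad2deg(atan2(x * sinc,
                                      rho * cos(p0) * cosc - y * sin(p0) * sinc)))
  list(lon = wrap_lon360(lon), lat = lat)
}

# Spherical centroid of a set of points; the per-animal projection centre.
track_centroid <- function(lon, lat) {
  p <- .deg2rad(lat); l <- .deg2rad(lon)
  x <- mean(cos(p) * cos(l)); y <- mean(cos(p) * sin(l)); z <- mean(sin(p))
  list(lon = wrap_lon360(.rad2deg(atan2(y, x))),
       lat = .rad2deg(atan2(z, sqrt(x^2 + y^2))))
}
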