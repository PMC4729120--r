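# Rhumb-line (loxodrome) geodesy on a sphere.
#
# A rhumb line crosses every meridian at the same angle, so its compass
# bearing is constant along the whole path.  That makes it the natural
# geometry for overwater flight bearings measured between two receiver
# towers: the reported angle is the heading a bird holding a fixed compass
# course would have flown.  All formulas use the Mercator-stretched latitude
# psi = ln(tan(pi/4 + phi/2)).

#' Mean Earth radius (km) used throughout
#'
#' IUGG mean radius of the sphere with the same volume-to-surface ratio as
#' the WGS84 ellipsoid.
#' @export
EARTH_RADIUS_KM <- 6371.0088

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

#' Normalize longitudes to (-180, 180]
#' @param lon longitude(s), decimal degrees
#' @return normalized longitude(s)
#' @export
normalize_lon <- function(lon) {
  out <- ((lon + 180) %% 360) - 180
  out[out == -180] <- 180
  out
}

.check_latlon <- function(lat, lon, what = "point") {
  if (any(!is.finite(lat)) || any(!is.finite(lon)))
    stop(what, ": non-finite coordinates")
  if (any(lat < -90 | lat > 90))
    stop(what, ": latitude outside [-90, 90]")
  invisible(TRUE)
}

# shortest-way longitude difference in radians
.dlon_rad <- function(lon1, lon2) {
  dl <- .deg2rad(normalize_lon(lon2 - lon1))
  dl
}

# Mercator-stretched latitude difference; guard the tan() poles
.dpsi <- function(phi1, phi2) {
  log(tan(pi / 4 + phi2 / 2) / tan(pi / 4 + phi1 / 2))
}

#' Rhumb-line bearing between two points
#'
#' Constant compass bearing of the loxodrome from \code{a} to \code{b},
#' clockwise from true north, in \code{[0, 360)}.  Longitude differences are
#' taken the shortest way around.  Identical points have no defined bearing
#' and raise an error.
#'
#' @param lat1,lon1 origin, decimal degrees (WGS84)
#' @param lat2,lon2 destination, decimal degrees
#' @return bearing in degrees, vectorized over inputs
#' @examples
#' rhumb_bearing(43, -65, 44, -65)   # due north: 0
#' rhumb_bearing(0, 0, 0, 10)        # along the equator: 90
#' @export
rhumb_bearing <- function(lat1, lon1, lat2, lon2) {
  .check_latlon(lat1, lon1, "origin")
  .check_latlon(lat2, lon2, "destination")
  if (any(lat1 == lat2 & normalize_lon(lon1) == normalize_lon(lon2)))
    stop("rhumb_bearing: undefined for identical points")
  phi1 <- .deg2rad(lat1); phi2 <- .deg2rad(lat2)
  dlon <- .dlon_rad(lon1, lon2)
  dpsi <- .dpsi(phi1, phi2)
  # near-meridian guard: avoid atan2 noise when the course is due N/S
  theta <- ifelse(abs(dlon) < 1e-12,
                  ifelse(phi2 > phi1, 0, pi),
                  atan2(dlon, dpsi))
  (.rad2deg(theta)) %% 360
}

#' Rhumb-line distance between two points
#'
#' Length of the loxodrome on a sphere of radius \code{EARTH_RADIUS_KM}.
#' Along a rhumb line latitude changes linearly with distance; the east-west
#' component scales with the cosine of latitude, using the Mercator latitude
#' to integrate exactly.
#'
#' @inheritParams rhumb_bearing
#' @return distance in kilometres, vectorized; 0 for identical points
#' @export
rhumb_distance <- function(lat1, lon1, lat2, lon2) {
  .check_latlon(lat1, lon1, "origin")
  .check_latlon(lat2, lon2, "destination")
  phi1 <- .deg2rad(lat1); phi2 <- .deg2rad(lat2)
  dphi <- phi2 - phi1
  dlon <- abs(.dlon_rad(lon1, lon2))
  dpsi <- .dpsi(phi1, phi2)
  # q = dphi/dpsi -> cos(phi) in the limit dphi -> 0
  q <- ifelse(abs(dpsi) > 1e-12, dphi / dpsi, cos(phi1))
  sqrt(dphi^2 + (q * dlon)^2) * EARTH_RADIUS_KM
}

#' Great-circle (haversine) distance, km
#'
#' Shortest-path distance on the sphere; used internally as a lower bound on
#' the rhumb distance and in tests.
#' @inheritParams rhumb_bearing
#' @return distance in kilometres
#' @export
haversine_distance <- function(lat1, lon1, lat2, lon2) {
  phi1 <- .deg2rad(lat1); phi2 <- .deg2rad(lat2)
  dphi <- phi2 - phi1
  dlon <- .dlon_rad(lon1, lon2)
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlon / 2)^2
  2 * asin(pmin(1, sqrt(a))) * EARTH_RADIUS_KM
}

#' Ground speed between two detections
#'
#' Rhumb-line distance divided by elapsed time: the straight-path speed a
#' bird must at least have sustained between two detections at different
#' sites.  Used to classify flights as direct.
#'
#' @inheritParams rhumb_bearing
#' @param t_depart,t_arrive POSIXct (or numeric seconds); \code{t_arrive}
#'   must be strictly later
#' @return speed in metres per second
#' @export
ground_speed <- function(lat1, lon1, lat2, lon2, t_depart, t_arrive) {
  dt <- as.numeric(t_arrive) - as.numeric(t_depart)
  if (any(dt <= 0)) stop("ground_speed: non-positive elapsed time")
  rhumb_distance(lat1, lon1, lat2, lon2) * 1000 / dt
}

#' Point a given fraction along a rhumb line
#'
#' Latitude varies linearly with distance along a loxodrome; longitude
#' follows from the constant course via the Mercator latitude.  Used by the
#' simulator to place a bird in mid-flight.
#'
#' @inheritParams rhumb_bearing
#' @param frac fraction(s) in \code{[0, 1]} of the way from a to b
#' @return list with components \code{lat}, \code{lon} (degrees)
#' @export
rhumb_point <- function(lat1, lon1, lat2, lon2, frac) {
  phi1 <- .deg2rad(lat1); phi2 <- .deg2rad(lat2)
  dlon <- .dlon_rad(lon1, lon2)
  phi <- phi1 + frac * (phi2 - phi1)
  dpsi_tot <- .dpsi(phi1, phi2)
  if (abs(dpsi_tot) > 1e-12) {
    lon <- lon1 + .rad2deg(dlon) * .dpsi(phi1, phi) / dpsi_tot
  } else {
    lon <- lon1 + frac * .rad2deg(dlon)   # east-west course
  }
  list(lat = .rad2deg(phi), lon = normalize_lon(lon))
}
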