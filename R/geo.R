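#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6371 km. All arguments are
#' recycled to a common length, so the function can be used on whole tracks
#' at once.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in WGS84 decimal degrees.
#' @return Distance(s) in kilometres.
#' @examples
#' great_circle_km(0, 0, 1, 0)   # one degree of a meridian, ~111.195 km
#' @export
great_circle_km <- function(lon1, lat1, lon2, lat2) {
  r <- 6371.0
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dp <- (lat2 - lat1) * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  a <- sin(dp / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  a <- pmin(pmax(a, 0), 1)
  2 * r * asin(sqrt(a))
}

#' Initial bearing from one point to another
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in decimal degrees.
#' @return Bearing in radians, measured clockwise from north, in (-pi, pi].
#' @export
initial_bearing_rad <- function(lon1, lat1, lon2, lat2) {
  p1 <- lat1 * pi / 180
  p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  y <- sin(dl) * cos(p2)
  x <- cos(p1) * sin(p2) - sin(p1) * cos(p2) * cos(dl)
  atan2(y, x)
}

#' Wrap an angle to (-pi, pi]
#'
#' The wrap convention maps -pi to +pi, so an exact reversal of direction is
#' reported as a turn of +pi.
#'
#' @param x Angle(s) in radians.
#' @return Wrapped angle(s) in (-pi, pi].
#' @export
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Azimuthal-equidistant projection to a local plane
#'
#' Projects lon/lat onto a plane tangent at `(center_lon, center_lat)` using
#' exact great-circle distance and bearing, so radial distances from the
#' center are preserved. Working units are kilometres; x points east, y
#' north. Used to put track segments into planar coordinates for the CTCRW
#' state-space model.
#'
#' @param lon,lat Coordinates in decimal degrees.
#' @param center_lon,center_lat Projection center in decimal degrees.
#' @return `project_aeq`: data.frame with columns `x`, `y` (km).
#' @export
project_aeq <- function(lon, lat, center_lon, center_lat) {
  d <- great_circle_km(center_lon, center_lat, lon, lat)
  b <- initial_bearing_rad(center_lon, center_lat, lon, lat)
  data.frame(x = d * sin(b), y = d * cos(b))
}

#' @rdname project_aeq
#' @param x,y Planar coordinates in km.
#' @return `unproject_aeq`: data.frame with columns `lon`, `lat` (degrees).
#' @export
unproject_aeq <- function(x, y, center_lon, center_lat) {
  r <- 6371.0
  d <- sqrt(x^2 + y^2)
  b <- atan2(x, y)
  p1 <- center_lat * pi / 180
  l1 <- center_lon * pi / 180
  ang <- d / r
  p2 <- asin(sin(p1) * cos(ang) + cos(p1) * sin(ang) * cos(b))
  l2 <- l1 + atan2(
    sin(b) * sin(ang) * cos(p1),
    cos(ang) - sin(p1) * sin(p2)
  )
  lon <- l2 * 180 / pi
  lon <- ((lon + 180) %% 360) - 180
  out <- data.frame(lon = lon, lat = p2 * 180 / pi)
  # degenerate at the exact center: bearing undefined, distance zero
  at0 <- d == 0
  out$lon[at0] <- center_lon
  out$lat[at0] <- center_lat
  out
}
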