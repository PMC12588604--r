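# Great-circle geometry on a sphere of radius 6371.0088 km.

EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance
#'
#' Haversine distance between two points (or vectors of points) on the sphere
#' of radius 6371.0088 km.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees.
#' @return Distance in kilometres.
#' @export
gc_distance <- function(lat1, lon1, lat2, lon2) {
  phi1 <- deg2rad(lat1); phi2 <- deg2rad(lat2)
  dphi <- deg2rad(lat2 - lat1); dlam <- deg2rad(lon2 - lon1)
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

#' Initial great-circle bearing
#'
#' Azimuth of the great circle from point 1 toward point 2 at point 1,
#' degrees clockwise from north, wrapped to \[0, 360).
#'
#' @inheritParams gc_distance
#' @return Bearing in degrees. Identical or antipodal point pairs are rejected
#'   (the bearing is undefined there).
#' @export
initial_bearing <- function(lat1, lon1, lat2, lon2) {
  same <- abs(lat1 - lat2) < 1e-12 & abs(wrap360(lon1 - lon2)) < 1e-12
  anti <- abs(lat1 + lat2) < 1e-9 & abs(abs(angle_diff(lon1, lon2)) - 180) < 1e-9
  if (any(same | anti)) {
    stop("initial bearing undefined for identical or antipodal points",
         call. = FALSE)
  }
  phi1 <- deg2rad(lat1); phi2 <- deg2rad(lat2)
  dlam <- deg2rad(lon2 - lon1)
  y <- sin(dlam) * cos(phi2)
  x <- cos(phi1) * sin(phi2) - sin(phi1) * cos(phi2) * cos(dlam)
  wrap360(rad2deg(atan2(y, x)))
}

# Abundance-weighted spherical centroid: mean of weighted unit vectors,
# renormalised back to the sphere. Returns c(lat, lon).
spherical_centroid <- function(lat, lon, w = NULL) {
  if (length(lat) == 0L) stop("no points for centroid", call. = FALSE)
  if (is.null(w)) w <- rep(1, length(lat))
  if (all(w == 0)) stop("all centroid weights are zero", call. = FALSE)
  phi <- deg2rad(lat); lam <- deg2rad(lon)
  x <- sum(w * cos(phi) * cos(lam)); y <- sum(w * cos(phi) * sin(lam))
  z <- sum(w * sin(phi))
  n <- sqrt(x^2 + y^2 + z^2)
  if (n < 1e-12) stop("degenerate centroid (weighted vectors cancel)", call. = FALSE)
  c(lat = rad2deg(asin(z / n)), lon = rad2deg(atan2(y / n, x / n)))
}
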