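# Lightweight lat-lon raster container used for both the coarse scenario grid
# and the finer feature layers. `z` is an nlat x nlon matrix (or array with a
# third dimension for monthly/DOY stacks); lat/lon are cell-centre vectors in
# ascending order.

#' Construct a gridded layer
#'
#' @param lat,lon Cell-centre coordinate vectors (ascending, degrees).
#' @param z Matrix `length(lat) x length(lon)` (or array with extra slices).
#' @return An object of class `ww_raster`.
#' @export
ww_raster <- function(lat, lon, z) {
  stopifnot(is.numeric(lat), is.numeric(lon))
  if (is.matrix(z) || is.array(z)) {
    stopifnot(dim(z)[1] == length(lat), dim(z)[2] == length(lon))
  } else stop("z must be a matrix or array")
  structure(list(lat = lat, lon = lon, z = z), class = "ww_raster")
}

#' @exportS3Method base::print
print.ww_raster <- function(x, ...) {
  cat(sprintf("<ww_raster> %d x %d cells, lat [%.2f, %.2f], lon [%.2f, %.2f]\n",
              length(x$lat), length(x$lon), min(x$lat), max(x$lat),
              min(x$lon), max(x$lon)))
  invisible(x)
}

# Index of the nearest cell centre; returns cbind(i, j).
raster_cell <- function(r, lat, lon) {
  i <- pmax(1L, pmin(length(r$lat), round(approx(r$lat, seq_along(r$lat),
       xout = lat, rule = 2)$y)))
  j <- pmax(1L, pmin(length(r$lon), round(approx(r$lon, seq_along(r$lon),
       xout = lon, rule = 2)$y)))
  cbind(i = as.integer(i), j = as.integer(j))
}

# Value of the (2-D) raster at point(s), nearest-cell lookup.
raster_at <- function(r, lat, lon, slice = NULL) {
  ij <- raster_cell(r, lat, lon)
  z <- if (is.null(slice)) r$z else r$z[, , slice]
  z[cbind(ij[, 1], ij[, 2])]
}

# Bilinear refinement of a 2-D layer onto a grid `factor` times finer.
# Used to build plausible fine-scale feature layers from coarse scenario
# fields; adds no information, only smooth interpolation.
raster_refine <- function(r, factor = 5L) {
  stopifnot(factor >= 1)
  flat <- seq(min(r$lat), max(r$lat), length.out = length(r$lat) * factor)
  flon <- seq(min(r$lon), max(r$lon), length.out = length(r$lon) * factor)
  zi <- apply(r$z, 2, function(col) approx(r$lat, col, xout = flat, rule = 2)$y)
  zf <- t(apply(zi, 1, function(row) approx(r$lon, row, xout = flon, rule = 2)$y))
  ww_raster(flat, flon, zf)
}

# Grid spec helper ------------------------------------------------------------

#' Default scenario grid specification
#'
#' The scenario grids default to ~1.9 deg latitude x 2.5 deg longitude
#' (the atmospheric component's horizontal resolution) over 0-60 N, 60-140 E,
#' but every bound and step is configurable so that small test grids run in
#' seconds.
#'
#' @param lat_min,lat_max,lon_min,lon_max Domain bounds (degrees).
#' @param dlat,dlon Cell sizes (degrees).
#' @return A list with class `ww_grid_spec`.
#' @export
grid_spec <- function(lat_min = 0, lat_max = 60, lon_min = 60, lon_max = 140,
                      dlat = 1.9, dlon = 2.5) {
  stopifnot(lat_max > lat_min, lon_max > lon_min, dlat > 0, dlon > 0)
  lat <- seq(lat_min + dlat / 2, lat_max, by = dlat)
  lon <- seq(lon_min + dlon / 2, lon_max, by = dlon)
  structure(list(lat = lat, lon = lon, dlat = dlat, dlon = dlon,
                 lat_min = lat_min, lat_max = lat_max,
                 lon_min = lon_min, lon_max = lon_max),
            class = "ww_grid_spec")
}
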