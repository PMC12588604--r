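# Topographic features: mean and sd of elevation, slope, northness, eastness
# over a square buffer (8 columns).

TOPO_COLS <- c("topo_elev_mean", "topo_elev_sd", "topo_slope_mean",
               "topo_slope_sd", "topo_north_mean", "topo_north_sd",
               "topo_east_mean", "topo_east_sd")

# Slope (radians) and aspect-derived northness/eastness from a DEM.
# Central differences in the interior, one-sided at edges. Aspect is the
# downslope direction, degrees clockwise from north; northness = cos(aspect),
# eastness = sin(aspect); flat cells (zero gradient) get 0 for both.
terrain_metrics <- function(dem) {
  z <- dem$z; nlat <- nrow(z); nlon <- ncol(z)
  dy_m <- diff(dem$lat[1:2]) * KM_PER_DEG * 1000
  dx_m <- diff(dem$lon[1:2]) * KM_PER_DEG * cos(deg2rad(mean(dem$lat))) * 1000
  gy <- z; gx <- z
  gy[1, ] <- (z[2, ] - z[1, ]) / dy_m
  gy[nlat, ] <- (z[nlat, ] - z[nlat - 1, ]) / dy_m
  if (nlat > 2) gy[2:(nlat - 1), ] <-
    (z[3:nlat, ] - z[1:(nlat - 2), ]) / (2 * dy_m)
  gx[, 1] <- (z[, 2] - z[, 1]) / dx_m
  gx[, nlon] <- (z[, nlon] - z[, nlon - 1]) / dx_m
  if (nlon > 2) gx[, 2:(nlon - 1)] <-
    (z[, 3:nlon] - z[, 1:(nlon - 2)]) / (2 * dx_m)
  g <- sqrt(gx^2 + gy^2)
  slope <- atan(g)
  north <- east <- matrix(0, nlat, nlon)
  nz <- g > 1e-12
  # downhill direction = -gradient; angle clockwise from north
  aspect <- atan2(-gx[nz], -gy[nz])
  north[nz] <- cos(aspect)
  east[nz] <- sin(aspect)
  list(slope = slope, north = north, east = east)
}

#' Topographic features over a buffered area
#'
#' Mean and standard deviation of elevation, slope (radians), northness and
#' eastness over the cells whose centres fall inside the
#' `buffer_km x buffer_km` square around the point. If the buffer misses the
#' DEM entirely, the nearest cell is used as a logged fallback.
#'
#' @param dem A `ww_raster` DEM in metres covering the buffer.
#' @param lat,lon Point coordinates (degrees).
#' @param buffer_km Buffer side length (default 3).
#' @return Named numeric vector of length 8.
#' @export
topographic_features <- function(dem, lat, lon, buffer_km = 3) {
  half_lat <- (buffer_km / 2) / KM_PER_DEG
  half_lon <- (buffer_km / 2) / (KM_PER_DEG * cos(deg2rad(lat)))
  sel_i <- which(abs(dem$lat - lat) <= half_lat + 1e-9)
  sel_j <- which(abs(dem$lon - lon) <= half_lon + 1e-9)
  if (length(sel_i) == 0L || length(sel_j) == 0L) {
    ij <- raster_cell(dem, lat, lon)
    sel_i <- ij[1]; sel_j <- ij[2]
    message("topographic buffer outside DEM; nearest-cell fallback used")
  }
  tm <- terrain_metrics(dem)
  sd0 <- function(x) if (length(x) > 1) sd(x) else 0
  vals <- lapply(list(dem$z, tm$slope, tm$north, tm$east),
                 function(m) as.vector(m[sel_i, sel_j, drop = FALSE]))
  out <- c(mean(vals[[1]]), sd0(vals[[1]]), mean(vals[[2]]), sd0(vals[[2]]),
           mean(vals[[3]]), sd0(vals[[3]]), mean(vals[[4]]), sd0(vals[[4]]))
  names(out) <- TOPO_COLS
  out
}
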