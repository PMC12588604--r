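# On-demand fine-scale feature layers. Storing a ~1 km global DEM / land
# cover raster is out of scope at desk scale, so local patches around a point
# are generated deterministically: the coarse scenario field is bilinearly
# interpolated and decorated with a hash-based (RNG-state-free) roughness
# field, so the same (env, lat, lon) always yields the same patch.

# Deterministic pseudo-random value in [0, 1) from integer km coordinates.
hash01 <- function(kx, ky, salt = 0) {
  v <- sin(kx * 12.9898 + ky * 78.233 + salt * 0.618034) * 43758.5453
  v - floor(v)
}

# Bilinear interpolation of a 2-D coarse layer at arbitrary points.
coarse_interp <- function(lat_axis, lon_axis, z, lat, lon) {
  fi <- approx(lat_axis, seq_along(lat_axis), xout = lat, rule = 2)$y
  fj <- approx(lon_axis, seq_along(lon_axis), xout = lon, rule = 2)$y
  i0 <- pmax(1L, pmin(length(lat_axis) - 1L, floor(fi))); i1 <- i0 + 1L
  j0 <- pmax(1L, pmin(length(lon_axis) - 1L, floor(fj))); j1 <- j0 + 1L
  wi <- clamp(fi - i0, 0, 1); wj <- clamp(fj - j0, 0, 1)
  z[cbind(i0, j0)] * (1 - wi) * (1 - wj) + z[cbind(i1, j0)] * wi * (1 - wj) +
    z[cbind(i0, j1)] * (1 - wi) * wj + z[cbind(i1, j1)] * wi * wj
}

# Local DEM patch (ww_raster, metres) centred on the point: `n` x `n` cells of
# `res_km` spacing. Roughness amplitude scales with local relief.
local_dem_patch <- function(env, lat, lon, n = 5L, res_km = 1) {
  off <- (seq_len(n) - (n + 1) / 2) * res_km
  plat <- lat + off / KM_PER_DEG
  plon <- lon + off / (KM_PER_DEG * cos(deg2rad(lat)))
  grid <- expand.grid(la = plat, lo = plon)
  base <- coarse_interp(env$lat, env$lon, env$layers$elevation,
                        grid$la, grid$lo)
  kx <- round(grid$lo * KM_PER_DEG * cos(deg2rad(lat)))
  ky <- round(grid$la * KM_PER_DEG)
  rough <- 30 * (2 * hash01(kx, ky, env$seed) - 1)
  z <- matrix(pmax(0, base + rough), n, n)
  ww_raster(plat, plon, z)
}

# Local land-cover patch: coarse class at each fine cell, with a deterministic
# speckle that occasionally swaps a cell to a neighbouring class so patches
# have internal structure.
local_lc_patch <- function(env, lat, lon, n = 5L, res_km = 1) {
  off <- (seq_len(n) - (n + 1) / 2) * res_km
  plat <- lat + off / KM_PER_DEG
  plon <- lon + off / (KM_PER_DEG * cos(deg2rad(lat)))
  grid <- expand.grid(la = plat, lo = plon)
  ij <- raster_cell(list(lat = env$lat, lon = env$lon), grid$la, grid$lo)
  cls <- env$layers$land_cover[cbind(ij[, 1], ij[, 2])]
  kx <- round(grid$lo * KM_PER_DEG * cos(deg2rad(lat)))
  ky <- round(grid$la * KM_PER_DEG)
  h <- hash01(kx, ky, env$seed + 7)
  swap <- h > 0.8
  cls[swap] <- pmax(1L, pmin(10L, cls[swap] +
                               ifelse(h[swap] > 0.9, 1L, -1L)))
  ww_raster(plat, plon, matrix(as.integer(cls), n, n))
}

# Daily series (365 values) from 12 monthly values by periodic linear
# interpolation at month mid-DOYs. `sum_to_daily` divides monthly totals by
# month length first (for precipitation).
daily_from_monthly <- function(vals12, sum_to_daily = FALSE) {
  v <- if (sum_to_daily) vals12 / MONTH_DAYS else vals12
  x <- c(MONTH_MIDS[12] - 365, MONTH_MIDS, MONTH_MIDS[1] + 365)
  y <- c(v[12], v, v[1])
  approx(x, y, xout = 1:365)$y
}

# NDVI observation series (doy, ndvi) at a point, from the coarse stack.
ndvi_series_at <- function(env, lat, lon) {
  ij <- raster_cell(list(lat = env$lat, lon = env$lon), lat, lon)
  data.frame(doy = env$params$ndvi_doys,
             ndvi = env$layers$ndvi[ij[1], ij[2], ])
}
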