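# Synthetic two-scenario environment generator.
#
# The generator emulates the statistical structure the downstream analysis
# assumes, not any climate model's physics: a plateau block whose elevation
# differs between the "modern" and "preuplift" scenarios (preuplift elevation
# capped at 300 m), seasonally reversing monsoon winds over the monsoon sector
# in the modern scenario only, latitudinal and elevational temperature
# gradients, orographic precipitation tied to the modern relief, and
# vegetation/NDVI responding to climate.

#' Default environment-generator parameters
#'
#' All tunables live here so the stated world is configured in one place.
#' Units: elevation m; winds m/s; temperature degC; precipitation mm/month;
#' lapse rate degC per km.
#'
#' @return Named list of parameters.
#' @export
env_params <- function() {
  list(
    plateau_lon = c(75, 105), plateau_lat = c(28, 38),  # plateau block (deg)
    plateau_base = 4500, plateau_relief = 700,          # block elevation range
    preuplift_cap = 300,                                # counterfactual cap (m)
    lapse_rate = 6.5,                                   # degC / km
    t_equator = 28, t_lat_gradient = 0.45,              # sea-level temperature
    t_seasonal_base = 2, t_seasonal_lat = 0.12,         # seasonal amplitude
    monsoon_lon = c(64, 120), monsoon_lat = c(5, 30),   # monsoon sector (deg)
    monsoon_u = 6, monsoon_v = 5,                       # monsoon wind amplitude
    p_base = 40, p_tropic = 120, p_monsoon = 220,       # precipitation terms
    monsoon_core_summer = 105, monsoon_core_winter = 70,# wet-core longitudes
    p_oro = 90,                                         # orographic coupling
    noise_wind = 0.3, noise_temp = 0.4, noise_precip = 5,
    ndvi_doys = seq(9, 365, by = 16)                    # 16-day composites (23)
  )
}

# Smooth seeded random field in [0, 1]: a few random-phase sinusoids.
smooth_field01 <- function(nlat, nlon, nwaves = 6) {
  latn <- matrix(seq(0, 1, length.out = nlat), nlat, nlon)
  lonn <- matrix(seq(0, 1, length.out = nlon), nlat, nlon, byrow = TRUE)
  f <- matrix(0, nlat, nlon)
  for (k in seq_len(nwaves)) {
    f <- f + runif(1, 0.3, 1) *
      sin(2 * pi * (runif(1, 0.5, 3) * latn + runif(1, 0.5, 3) * lonn) +
          runif(1, 0, 2 * pi))
  }
  (f - min(f)) / max(1e-12, diff(range(f)))
}

# Smooth 0/1 ramp indicator of a lon/lat box with soft edges (degrees).
soft_box <- function(lat_m, lon_m, lat_rng, lon_rng, soft = 3) {
  ramp <- function(x, lo, hi) plogis((x - lo) / soft) * plogis((hi - x) / soft)
  ramp(lat_m, lat_rng[1], lat_rng[2]) * ramp(lon_m, lon_rng[1], lon_rng[2])
}

#' Generate a scenario environment stack
#'
#' Deterministic given `seed`. The modern scenario carries the plateau block
#' (elevation >= 4000 m inside the block) with seasonally reversing monsoon
#' winds and orographic precipitation; the preuplift counterfactual caps
#' elevation at 300 m and has predominantly zonal winds and smoother
#' precipitation. Temperature decreases with latitude and with elevation at
#' the configured lapse rate.
#'
#' @param scenario `"modern"` or `"preuplift"`.
#' @param seed Integer seed; the generator is a pure function of
#'   (parameters, seed).
#' @param grid A [grid_spec()].
#' @param params Parameter list as from [env_params()].
#' @return An `EnvironmentStack`: scenario label, grid, and layers
#'   `elevation` (matrix), `u_wind`/`v_wind`/`temperature`/`precipitation`
#'   (nlat x nlon x 12 arrays), `vegetation_fraction`, `land_cover`
#'   (matrices), `ndvi` (nlat x nlon x 23 array, 16-day DOYs in
#'   `params$ndvi_doys`).
#' @export
generate_environment <- function(scenario, seed, grid = grid_spec(),
                                 params = env_params()) {
  stopifnot_scalar_in(scenario, c("modern", "preuplift"), "scenario")
  lat <- grid$lat; lon <- grid$lon
  nlat <- length(lat); nlon <- length(lon)
  lat_m <- matrix(lat, nlat, nlon)
  lon_m <- matrix(lon, nlat, nlon, byrow = TRUE)
  p <- params

  with_seed(seed, {
    # --- elevation -----------------------------------------------------------
    base_elev <- 280 * smooth_field01(nlat, nlon)           # lowland terrain
    plateau_bump <- smooth_field01(nlat, nlon)
    in_block <- lat_m >= p$plateau_lat[1] & lat_m <= p$plateau_lat[2] &
      lon_m >= p$plateau_lon[1] & lon_m <= p$plateau_lon[2]
    taper <- soft_box(lat_m, lon_m, p$plateau_lat, p$plateau_lon, soft = 1.5)
    plateau_elev <- p$plateau_base + p$plateau_relief * plateau_bump
    if (scenario == "modern") {
      elev <- base_elev + (plateau_elev - base_elev) * taper
      elev[in_block] <- plateau_elev[in_block]              # block >= 4000 m
    } else {
      elev <- pmin(base_elev, p$preuplift_cap)
    }

    # --- winds ---------------------------------------------------------------
    u_bg <- 8 * exp(-((lat_m - 45) / 12)^2) - 3 * exp(-((lat_m - 10) / 10)^2)
    monsoon_w <- soft_box(lat_m, lon_m, p$monsoon_lat, p$monsoon_lon)
    u_wind <- v_wind <- temperature <- precipitation <-
      array(0, c(nlat, nlon, 12))
    relief <- local({
      gy <- rbind(elev[2, ] - elev[1, ],
                  (elev[-(1:2), ] - elev[-c(nlat - 1, nlat), ]) / 2,
                  elev[nlat, ] - elev[nlat - 1, ])
      gx <- cbind(elev[, 2] - elev[, 1],
                  (elev[, -(1:2)] - elev[, -c(nlon - 1, nlon)]) / 2,
                  elev[, nlon] - elev[, nlon - 1])
      pmin(1, sqrt(gx^2 + gy^2) / 2000)                    # 0..1 relief index
    })
    seas_amp <- p$t_seasonal_base + p$t_seasonal_lat * lat_m
    for (m in 1:12) {
      s <- cos(2 * pi * (m - 7) / 12)                       # +1 Jul, -1 Jan
      if (scenario == "modern") {
        u <- u_bg + p$monsoon_u * s * monsoon_w
        v <- p$monsoon_v * s * monsoon_w
      } else {
        u <- u_bg * (1 + 0.1 * s)
        v <- matrix(0, nlat, nlon)
      }
      u_wind[, , m] <- u + p$noise_wind * (2 * smooth_field01(nlat, nlon) - 1)
      v_wind[, , m] <- v + p$noise_wind * (2 * smooth_field01(nlat, nlon) - 1)

      temperature[, , m] <- p$t_equator - p$t_lat_gradient * lat_m -
        p$lapse_rate * elev / 1000 + seas_amp * s +
        p$noise_temp * (2 * smooth_field01(nlat, nlon) - 1)

      prec <- p$p_base + p$p_tropic * exp(-(lat_m / 15)^2)
      if (scenario == "modern") {
        # monsoon rains whose wet core slides zonally with the seasonal
        # phase: the summer (southwest) monsoon soaks the east of the
        # sector, the winter northeast monsoon shifts the rains toward its
        # southwest
        wet_core <- (p$monsoon_core_summer + p$monsoon_core_winter) / 2 +
          (p$monsoon_core_summer - p$monsoon_core_winter) / 2 * s
        zonal_w <- exp(-((lon_m - wet_core) / 12)^2)
        prec <- prec + p$p_monsoon * monsoon_w * zonal_w +
          p$p_oro * relief * (1 + pmax(s, 0))
      }
      precipitation[, , m] <- pmax(0, prec +
        p$noise_precip * (2 * smooth_field01(nlat, nlon) - 1))
    }

    # --- vegetation, land cover, NDVI ---------------------------------------
    t_ann <- apply(temperature, c(1, 2), mean)
    p_ann <- apply(precipitation, c(1, 2), sum)
    veg <- clamp(plogis((p_ann - 600) / 300) *
                   clamp((t_ann + 5) / 25, 0.05, 1), 0, 1)
    land_cover <- land_cover_classes(elev, t_ann, p_ann, veg)

    doys <- p$ndvi_doys
    ndvi <- array(0, c(nlat, nlon, length(doys)))
    w_lat <- clamp(lat_m / 60, 0, 1)
    for (k in seq_along(doys)) {
      bell <- exp(-((doys[k] - 200) / 60)^2)
      season <- (1 - w_lat) + w_lat * bell
      ndvi[, , k] <- clamp(veg * (0.15 + 0.75 * season) - 0.05 +
                             0.01 * (2 * smooth_field01(nlat, nlon) - 1),
                           -1, 1)
    }

    structure(list(
      scenario = scenario, lat = lat, lon = lon, grid = grid, params = p,
      seed = as.integer(seed),
      layers = list(elevation = elev, u_wind = u_wind, v_wind = v_wind,
                    temperature = temperature, precipitation = precipitation,
                    vegetation_fraction = veg, land_cover = land_cover,
                    ndvi = ndvi)
    ), class = "EnvironmentStack")
  })
}

# Ten-class deterministic land-cover legend from climate + terrain.
# 1 barren, 2 sparse, 3 grassland, 4 shrubland, 5 cropland, 6 deciduous
# forest, 7 evergreen forest, 8 wetland, 9 snow/ice, 10 urban.
land_cover_classes <- function(elev, t_ann, p_ann, veg) {
  lc <- matrix(3L, nrow(elev), ncol(elev))
  lc[veg < 0.12] <- 1L
  lc[veg >= 0.12 & veg < 0.25] <- 2L
  lc[veg >= 0.40 & veg < 0.55] <- 4L
  lc[veg >= 0.55 & veg < 0.70 & t_ann > 8] <- 5L
  lc[veg >= 0.70 & t_ann <= 15] <- 6L
  lc[veg >= 0.70 & t_ann > 15] <- 7L
  lc[p_ann > 1800 & veg >= 0.55] <- 8L
  lc[elev > 5000 | t_ann < -12] <- 9L
  # deterministic sparse "urban" speckle in warm lowlands
  urb <- (round(elev * 7 + t_ann * 13) %% 97) == 0 & elev < 500 & t_ann > 10
  lc[urb] <- 10L
  lc
}

#' @exportS3Method base::print
print.EnvironmentStack <- function(x, ...) {
  cat(sprintf("<EnvironmentStack '%s'> %d x %d cells, seed %d\n",
              x$scenario, length(x$lat), length(x$lon), x$seed))
  cat(sprintf("  elevation [%.0f, %.0f] m; layers: %s\n",
              min(x$layers$elevation), max(x$layers$elevation),
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

# Annual summary layers used by the niche model and driver annotation:
# mean annual temperature (degC), total annual precipitation (mm/yr),
# elevation (m), vegetation fraction.
env_annual_layers <- function(env) {
  list(temperature = apply(env$layers$temperature, c(1, 2), mean),
       precipitation = apply(env$layers$precipitation, c(1, 2), sum),
       elevation = env$layers$elevation,
       vegetation = env$layers$vegetation_fraction)
}

# Nearest-cell matrix indices on the scenario grid.
env_cell <- function(env, lat, lon) {
  raster_cell(list(lat = env$lat, lon = env$lon), lat, lon)
}
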