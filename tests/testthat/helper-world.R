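# Shared desk-scale synthetic world, built once per test run.
# 20 x 30 cells over 0-60 N, 60-140 E (the small-grid configuration the
# generators are parameterised for).

tiny_grid <- function() grid_spec(0, 60, 60, 140, dlat = 3, dlon = 8 / 3)

world_cache <- new.env(parent = emptyenv())

test_world <- function() {
  if (is.null(world_cache$w)) {
    env_m <- generate_environment("modern", 101, tiny_grid())
    env_p <- generate_environment("preuplift", 101, tiny_grid())
    truth <- generate_species_truth(env_m, 3, 102)
    sim <- generate_checklists(truth, 40, 3000, 1.5, 103)
    world_cache$w <- list(env_m = env_m, env_p = env_p, truth = truth,
                          sim = sim)
  }
  world_cache$w
}

# Tiny flat-topped analytic DEM helpers for topographic tests.
plane_dem <- function(slope_north = 0, slope_east = 0, base = 500,
                      n = 7, res_km = 1, lat0 = 20, lon0 = 100) {
  off <- (seq_len(n) - (n + 1) / 2) * res_km
  lat <- lat0 + off / windward:::KM_PER_DEG
  lon <- lon0 + off / (windward:::KM_PER_DEG * cos(lat0 * pi / 180))
  y_m <- outer(off * 1000, rep(1, n))          # northward metres
  x_m <- outer(rep(1, n), off * 1000)          # eastward metres
  ww_raster(lat, lon, base + slope_north * y_m + slope_east * x_m)
}
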