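# Synthetic tracking routes: ordered breeding -> stopovers -> wintering node
# sequences following the seasonal suitability gradient, with ground-truth
# stopover labels. Individuals of a species breed at different sites within
# the range: breeding/wintering cells are sampled from the weekly
# suitability surfaces (wintering biased toward the individual's breeding
# site, stopovers toward the great-circle path), so routes spread across the
# species' full longitudinal extent.

#' Generate synthetic tracking routes
#'
#' @param truth A `SpeciesTruthSet`.
#' @param n_individuals Number of routes to generate (species are cycled).
#' @param seed Integer seed.
#' @param n_stopovers Stopovers per route (default 3).
#' @param winter_scale_km Distance scale biasing wintering-site choice toward
#'   the breeding site (default 2000 km).
#' @param stop_scale_km Distance scale keeping stopovers near the
#'   breeding-wintering path (default 500 km).
#' @return data.table with columns `individual_id`, `species_id`, `order`,
#'   `lat`, `lon`, `week`, `label` (breeding/stopover/wintering), and a
#'   `migratory` flag (FALSE collapses the route to one stationary cluster).
#' @export
generate_tracks <- function(truth, n_individuals, seed, n_stopovers = 3L,
                            winter_scale_km = 2000, stop_scale_km = 500) {
  stopifnot(inherits(truth, "SpeciesTruthSet"))
  if (n_individuals < 1) stop("`n_individuals` must be >= 1", call. = FALSE)
  env <- truth$env
  sp_ids <- truth$species$species_id
  nlat <- length(env$lat); nlon <- length(env$lon)
  lat_v <- rep(env$lat, nlon)
  lon_v <- rep(env$lon, each = nlat)
  breed_w <- 26:30; winter_w <- c(1:4, 50:52)
  mean_suit <- function(spid, weeks) {
    arr <- truth$suitability[[spid]]
    as.vector(apply(arr[, , weeks, drop = FALSE], c(1, 2), mean))
  }

  with_seed(seed, {
    out <- vector("list", n_individuals)
    for (i in seq_len(n_individuals)) {
      spid <- sp_ids[((i - 1L) %% length(sp_ids)) + 1L]
      sb <- mean_suit(spid, breed_w)
      sw <- mean_suit(spid, winter_w)
      if (all(sb == 0) || all(sw == 0)) {
        stop(sprintf("species %s has an empty seasonal range", spid))
      }
      b <- sample.int(length(sb), 1L, prob = sb)
      d_from_b <- gc_distance(lat_v[b], lon_v[b], lat_v, lon_v)
      if (sw[b] >= truth$threshold) {
        wcell <- b          # site fidelity: breeding cell suitable year-round
      } else {
        wgt <- sw * exp(-d_from_b / winter_scale_km)
        wcell <- sample.int(length(sw), 1L, prob = wgt)
      }
      migratory <- d_from_b[wcell] > 50

      if (migratory) {
        stop_weeks <- round(seq(32, 48, length.out = n_stopovers))
        frac <- seq_len(n_stopovers) / (n_stopovers + 1)
        stops <- integer(n_stopovers)
        for (k in seq_len(n_stopovers)) {
          path_lat <- lat_v[b] + frac[k] * (lat_v[wcell] - lat_v[b])
          path_lon <- lon_v[b] + frac[k] * (lon_v[wcell] - lon_v[b])
          sk <- mean_suit(spid, stop_weeks[k])
          dk <- gc_distance(path_lat, path_lon, lat_v, lon_v)
          wk_ <- sk * exp(-dk / stop_scale_km) + 1e-10
          stops[k] <- sample.int(length(sk), 1L, prob = wk_)
        }
        cells <- c(b, stops, wcell)
        nodes <- data.table::data.table(
          order = seq_len(n_stopovers + 2L),
          lat = lat_v[cells], lon = lon_v[cells],
          week = c(28L, stop_weeks, 52L),
          label = c("breeding", rep("stopover", n_stopovers), "wintering"))
      } else {
        nodes <- data.table::data.table(
          order = 1:2, lat = rep(lat_v[b], 2), lon = rep(lon_v[b], 2),
          week = c(28L, 52L), label = c("breeding", "wintering"))
      }
      nodes[, `:=`(lat = lat + runif(.N, -env$grid$dlat, env$grid$dlat) / 2,
                   lon = lon + runif(.N, -env$grid$dlon, env$grid$dlon) / 2)]
      nodes[, `:=`(individual_id = sprintf("IND%03d", i), species_id = spid,
                   migratory = migratory)]
      out[[i]] <- nodes
    }
    data.table::rbindlist(out)[, .(individual_id, species_id, order, lat, lon,
                                   week, label, migratory)]
  })
}
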