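# Wind-cost connectivity: monthly directed Moore-neighbourhood graphs whose
# edge costs decrease with tailwind, sampled least-cost-path betweenness as
# the connectivity map, and its affine reversal into the wind-cost layer used
# as a migration-direction driver.

#' Wind speed and blow-toward direction
#'
#' Convention (used everywhere in the package): u positive eastward, v
#' positive northward; direction is where the wind blows TOWARD, degrees
#' clockwise from north, so (u=1, v=0) -> 90. Calm air (0, 0) returns
#' direction 0 by convention.
#'
#' @param u,v Wind components (m/s).
#' @return List with `speed` and `direction` (degrees).
#' @export
wind_polar <- function(u, v) {
  stopifnot(all(is.finite(u)), all(is.finite(v)))
  speed <- sqrt(u^2 + v^2)
  direction <- ifelse(speed == 0, 0, wrap360(rad2deg(atan2(u, v))))
  list(speed = speed, direction = direction)
}

#' Monthly wind-cost edge graph
#'
#' For the edge from cell o to Moore-neighbour t with great-circle bearing b,
#' with wind (speed ws, direction theta) at o, the tailwind component is
#' `ws * cos(theta - b)` and the edge cost is
#' `d(o, t) * exp(-tailwind / s0)` with d the great-circle neighbour distance
#' (km) and scale `s0` (default 5 m/s): strictly positive, decreasing in
#' tailwind, increasing in headwind; calm air leaves pure distance costs.
#'
#' @param env An `EnvironmentStack` (or a list with `lat`, `lon`, and
#'   `layers$u_wind`/`layers$v_wind` monthly arrays).
#' @param month Month 1-12.
#' @param s0 Tailwind scale (m/s).
#' @return `WindCostGraph`: list with `edges` (data.table `from`, `to`,
#'   `cost`, `bearing`), `cells` (data.table `cell`, `lat`, `lon`), and the
#'   igraph object `g`.
#' @export
edge_costs <- function(env, month, s0 = 5) {
  stopifnot(month %in% 1:12)
  lat <- env$lat; lon <- env$lon
  nlat <- length(lat); nlon <- length(lon)
  u <- env$layers$u_wind[, , month]
  v <- env$layers$v_wind[, , month]
  cells <- data.table::data.table(
    cell = seq_len(nlat * nlon),
    i = rep(seq_len(nlat), nlon), j = rep(seq_len(nlon), each = nlat))
  cells[, `:=`(lat = lat[i], lon = lon[j])]
  wp <- wind_polar(as.vector(u), as.vector(v))

  moves <- expand.grid(di = -1:1, dj = -1:1)
  moves <- moves[!(moves$di == 0 & moves$dj == 0), ]
  elist <- vector("list", nrow(moves))
  for (m in seq_len(nrow(moves))) {
    di <- moves$di[m]; dj <- moves$dj[m]
    oi <- cells$i; oj <- cells$j
    ti <- oi + di; tj <- oj + dj
    ok <- ti >= 1 & ti <= nlat & tj >= 1 & tj <= nlon
    from <- cells$cell[ok]
    to <- (tj[ok] - 1L) * nlat + ti[ok]
    b <- initial_bearing(lat[oi[ok]], lon[oj[ok]], lat[ti[ok]], lon[tj[ok]])
    d <- gc_distance(lat[oi[ok]], lon[oj[ok]], lat[ti[ok]], lon[tj[ok]])
    tailwind <- wp$speed[from] * cos(deg2rad(wp$direction[from] - b))
    elist[[m]] <- data.table::data.table(
      from = from, to = to, bearing = b, cost = d * exp(-tailwind / s0))
  }
  edges <- data.table::rbindlist(elist)
  drop <- !is.finite(edges$cost)
  if (any(drop)) {
    message(sprintf("edge_costs: dropped %d edge(s) with missing wind", sum(drop)))
    edges <- edges[!drop]
  }
  g <- igraph::graph_from_data_frame(
    edges[, .(from, to, weight = cost)], directed = TRUE,
    vertices = data.frame(name = cells$cell))
  structure(list(edges = edges, cells = cells[, .(cell, lat, lon)], g = g,
                 month = month, s0 = s0, scenario = env$scenario %||% NA),
            class = "WindCostGraph")
}

#' Sampled least-cost-path connectivity map
#'
#' Samples `n_pairs` origin-destination cell pairs uniformly (seeded),
#' computes the least-cost (Dijkstra) path for each, and scores every cell by
#' the fraction of sampled paths passing through it. `all_pairs = TRUE`
#' enumerates every ordered pair instead (grids <= 2500 cells).
#'
#' @param graph A `WindCostGraph`.
#' @param n_pairs Number of sampled pairs (default 500).
#' @param seed Integer seed.
#' @param all_pairs Enumerate all ordered pairs instead of sampling.
#' @return data.table `cell`, `lat`, `lon`, `connectivity`.
#' @export
connectivity_map <- function(graph, n_pairs = 500L, seed = 1L,
                             all_pairs = FALSE) {
  nc <- nrow(graph$cells)
  if (all_pairs) {
    if (nc > 2500) stop("all-pairs mode limited to grids <= 2500 cells",
                        call. = FALSE)
    pairs <- as.matrix(expand.grid(o = seq_len(nc), d = seq_len(nc)))
    pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  } else {
    pairs <- with_seed(seed, {
      o <- sample.int(nc, n_pairs, replace = TRUE)
      d <- sample.int(nc, n_pairs, replace = TRUE)
      fix <- o == d
      d[fix] <- (d[fix] %% nc) + 1L
      cbind(o = o, d = d)
    })
  }
  counts <- numeric(nc)
  used <- 0L
  for (o in unique(pairs[, 1])) {
    dests <- pairs[pairs[, 1] == o, 2]
    sp <- suppressWarnings(igraph::shortest_paths(
      graph$g, from = as.character(o), to = as.character(dests),
      mode = "out", output = "vpath"))
    for (k in seq_along(sp$vpath)) {
      vp <- as.integer(igraph::as_ids(sp$vpath[[k]]))
      if (length(vp) == 0L) {
        message(sprintf("connectivity_map: unreachable pair (%d -> %d) skipped",
                        o, dests[k]))
        next
      }
      counts[vp] <- counts[vp] + 1
      used <- used + 1L
    }
  }
  out <- data.table::copy(graph$cells)
  out[, connectivity := counts / max(1L, used)]
  out[]
}

#' Reverse a connectivity map into a wind-cost layer
#'
#' Affine reversal `cost = max(connectivity) - connectivity`: the rank order
#' is exactly inverted (high connectivity = low wind cost) while the scale is
#' preserved for downstream standardised regression.
#'
#' @param connectivity Output of [connectivity_map()].
#' @return `WindCostLayer` data.table `cell`, `lat`, `lon`, `wind_cost`.
#' @export
reverse_to_cost_layer <- function(connectivity) {
  stopifnot(all(is.finite(connectivity$connectivity)))
  out <- data.table::copy(data.table::as.data.table(connectivity))
  if (diff(range(out$connectivity)) == 0) {
    warning("constant connectivity: wind-cost layer is constant zero")
  }
  out[, wind_cost := max(connectivity) - connectivity]
  out[, connectivity := NULL]
  out[]
}

#' Seasonal wind-cost layer
#'
#' Convenience wrapper: builds monthly graphs, averages the monthly
#' connectivity maps over the requested months (monthly layers aggregate to
#' the seasonal/annual layer by mean), and reverses the result.
#'
#' @param env `EnvironmentStack`.
#' @param months Months to aggregate (default all 12).
#' @param n_pairs,seed,s0 Passed through.
#' @return `WindCostLayer` data.table.
#' @export
wind_cost_layer <- function(env, months = 1:12, n_pairs = 300L, seed = 1L,
                            s0 = 5) {
  conn <- NULL
  for (m in months) {
    g <- edge_costs(env, m, s0 = s0)
    cm <- connectivity_map(g, n_pairs = n_pairs, seed = seed + m)
    conn <- if (is.null(conn)) cm else {
      conn$connectivity <- conn$connectivity + cm$connectivity
      conn
    }
  }
  conn$connectivity <- conn$connectivity / length(months)
  reverse_to_cost_layer(conn)
}
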