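# Migration geometry: weekly distribution centroids, stationary-period
# (breeding/wintering) delineation, great-circle segments with azimuth,
# season, longitudinal stage and direction class, and direction roses.

STAGE_WEST_LON <- 73    # stage bands: west lon < 73 E,
STAGE_EAST_LON <- 105   # central 73 <= lon < 105, east lon >= 105

#' Weekly abundance-weighted centroids
#'
#' Abundance-weighted spherical centroid (mean of weighted unit vectors,
#' renormalised) of the unmasked cells of each week. All-masked weeks yield a
#' missing centroid, linearly interpolated from neighbouring weeks with a log
#' entry.
#'
#' @param dist A `WeeklyDistribution` (possibly covering many weeks).
#' @return data.table `week`, `lat`, `lon`.
#' @export
weekly_centroid <- function(dist) {
  d <- data.table::as.data.table(dist)
  out <- d[masked == FALSE & is.finite(abundance),
           {
             cen <- spherical_centroid(lat, lon, abundance)
             .(lat = cen[1], lon = cen[2])
           }, by = week]
  all_weeks <- sort(unique(d$week))
  miss <- setdiff(all_weeks, out$week)
  if (length(miss)) {
    message(sprintf("weekly_centroid: interpolating %d all-masked week(s)",
                    length(miss)))
    out <- out[data.table::data.table(week = all_weeks), on = "week"]
    out[, lat := approx(week[!is.na(lat)], lat[!is.na(lat)], week, rule = 2)$y]
    out[, lon := approx(week[!is.na(lon)], lon[!is.na(lon)], week, rule = 2)$y]
  }
  data.table::setorder(out, week)
  out[]
}

#' Breeding and wintering stationary periods
#'
#' Finds the runs of consecutive weeks (cyclic over the year) whose
#' week-to-week centroid displacement stays below `threshold_km`; the two
#' longest runs are the stationary periods, the one overlapping midsummer
#' (weeks 22-35) is breeding and the other wintering, and their mean
#' centroids are the breeding/wintering centres. A track with fewer than two
#' stationary runs (e.g. a resident with one year-long run) is flagged
#' non-migratory.
#'
#' @param centroid_track Output of [weekly_centroid()] (>= 40 weeks).
#' @param threshold_km Stationarity threshold (default 100 km/week).
#' @return List: `migratory` flag, and when migratory `breeding` /
#'   `wintering` (each: `weeks`, `lat`, `lon`).
#' @export
stationary_periods <- function(centroid_track, threshold_km = 100) {
  tr <- data.table::as.data.table(centroid_track)
  data.table::setorder(tr, week)
  n <- nrow(tr)
  if (n < 40L) stop("need >= 40 weekly centroids", call. = FALSE)
  nxt <- c(2:n, 1L)
  step <- gc_distance(tr$lat, tr$lon, tr$lat[nxt], tr$lon[nxt])
  slow <- step < threshold_km          # week w -> w+1 below threshold
  # cyclic runs of consecutive slow steps; run of steps w..(w+k) spans
  # weeks w..(w+k+1)
  if (all(slow)) {
    return(list(migratory = FALSE, reason = "single year-long stationary run"))
  }
  r <- rle(slow)
  # rotate so the sequence starts at a non-slow step, making runs non-cyclic
  first_fast <- which(!slow)[1]
  idx <- c(first_fast:n, seq_len(first_fast - 1L))
  slow_rot <- slow[idx]
  rr <- rle(slow_rot)
  ends <- cumsum(rr$lengths)
  starts <- ends - rr$lengths + 1L
  runs <- which(rr$values)
  if (length(runs) < 2L) {
    return(list(migratory = FALSE, reason = "fewer than two stationary runs"))
  }
  lens <- rr$lengths[runs]
  top2 <- runs[order(lens, decreasing = TRUE)[1:2]]
  run_weeks <- lapply(top2, function(k) {
    steps <- idx[starts[k]:ends[k]]
    weeks <- unique(c(steps, (steps %% n) + 1L))   # steps span week w..w+1
    tr$week[weeks]
  })
  summer_score <- vapply(run_weeks, function(w) sum(w %in% 22:35), 0)
  breed_i <- which.max(summer_score)
  winter_i <- setdiff(1:2, breed_i)
  mk <- function(w) {
    sel <- tr[week %in% w]
    cen <- spherical_centroid(sel$lat, sel$lon)
    list(weeks = sort(w), lat = cen[1], lon = cen[2])
  }
  list(migratory = TRUE, breeding = mk(run_weeks[[breed_i]]),
       wintering = mk(run_weeks[[winter_i]]))
}

#' Build migration segments from ordered route nodes
#'
#' One directed segment per adjacent node pair, with the great-circle initial
#' bearing (azimuth), distance, season (autumn on the breeding-to-wintering
#' leg, spring on the reverse), longitudinal stage from the segment midpoint
#' (west lon < 73 E; central 73 <= lon < 105; east lon >= 105), and direction
#' class: latitudinal when the azimuth lies within 45 degrees of north or
#' south (boundary inclusive), longitudinal otherwise.
#'
#' @param nodes data.frame ordered along the route with `lat`, `lon`, `week`,
#'   `label` (first and last must be breeding/wintering endpoints). A route
#'   flagged `migratory = FALSE` yields zero segments.
#' @param species Species label attached to the segments.
#' @param season Optional override; inferred from the endpoint labels when
#'   NULL.
#' @return `MigrationSegment` data.table.
#' @export
build_segments <- function(nodes, species = NA_character_, season = NULL) {
  nd <- data.table::as.data.table(nodes)
  empty <- data.table::data.table(
    species = character(), from_lat = numeric(), from_lon = numeric(),
    to_lat = numeric(), to_lon = numeric(), azimuth = numeric(),
    distance_km = numeric(), season = character(), stage = character(),
    direction_class = character())
  if ("migratory" %in% names(nd) && !any(nd$migratory)) return(empty)
  if (nrow(nd) < 2L) return(empty)
  if ("order" %in% names(nd)) data.table::setorder(nd, order)
  if ("week" %in% names(nd) && is.unsorted(nd$week)) {
    stop("route nodes are not ordered in time", call. = FALSE)
  }
  if (is.null(season)) {
    season <- if (nd$label[1] == "breeding") "autumn" else "spring"
  }
  i <- seq_len(nrow(nd) - 1L)
  az <- initial_bearing(nd$lat[i], nd$lon[i], nd$lat[i + 1], nd$lon[i + 1])
  dist <- gc_distance(nd$lat[i], nd$lon[i], nd$lat[i + 1], nd$lon[i + 1])
  mid_lon <- (nd$lon[i] + nd$lon[i + 1]) / 2
  seg <- data.table::data.table(
    species = species,
    from_lat = nd$lat[i], from_lon = nd$lon[i],
    to_lat = nd$lat[i + 1], to_lon = nd$lon[i + 1],
    azimuth = az, distance_km = dist, season = season,
    stage = stage_of_lon(mid_lon),
    direction_class = direction_class(az))
  seg
}

#' Longitudinal stage band of a longitude
#' @param lon Longitude (degrees E).
#' @return `"west"`, `"central"` or `"east"`.
#' @export
stage_of_lon <- function(lon) {
  ifelse(lon < STAGE_WEST_LON, "west",
         ifelse(lon < STAGE_EAST_LON, "central", "east"))
}

#' Direction class of an azimuth
#'
#' Latitudinal if the minimal angular distance to north (0) or south (180)
#' is <= 45 degrees (boundary assigned latitudinal), else longitudinal.
#' @param azimuth Degrees.
#' @return Character vector.
#' @export
direction_class <- function(azimuth) {
  d <- pmin(abs(angle_diff(azimuth, 0)), abs(angle_diff(azimuth, 180)))
  ifelse(d <= 45, "latitudinal", "longitudinal")
}

#' Direction rose
#'
#' Counts over 16 equal azimuth sectors (22.5 degrees, first sector centred
#' on 0 spans \[-11.25, 11.25)), the circular mean, and the resultant length.
#'
#' @param azimuths Vector of azimuths (degrees).
#' @return List: `counts` (named 16-vector, sums to the input length),
#'   `circular_mean` (degrees), `resultant_length` in \[0, 1\].
#' @export
direction_rose <- function(azimuths) {
  if (length(azimuths) == 0L) stop("need >= 1 azimuth", call. = FALSE)
  sector <- (floor(wrap360(azimuths + 11.25) / 22.5) %% 16) + 1
  counts <- tabulate(sector, nbins = 16)
  names(counts) <- sprintf("%.1f", (0:15) * 22.5)
  s <- mean(sin(deg2rad(azimuths))); c <- mean(cos(deg2rad(azimuths)))
  list(counts = counts,
       circular_mean = wrap360(rad2deg(atan2(s, c))),
       resultant_length = sqrt(s^2 + c^2))
}
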