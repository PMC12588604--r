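# Checklist quality control: observer-expertise proxy, effort filters, and
# hex-binned spatiotemporal subsampling.

#' Default QC rules
#'
#' The effort and expertise filtering rules: complete checklists only;
#' Traveling or Stationary protocols; Traveling distance < 3 km; duration
#' strictly between 5 and 300 minutes; observer expertise percentile >= 2.5.
#'
#' @return Named list of rule parameters.
#' @export
qc_rules <- function() {
  list(max_distance_km = 3, min_duration_min = 5, max_duration_min = 300,
       min_expertise_pct = 2.5, protocols = c("Traveling", "Stationary"))
}

#' Observer expertise from historical checklists
#'
#' Expertise is the historical cumulative species count: the number of
#' distinct species an observer reported before the study year. The
#' percentile rank is the midrank empirical CDF,
#' `100 * (#\{count < c\} + 0.5 * #\{count == c\}) / n`, so ties share one
#' percentile and the lowest of 40 distinct counts sits at 1.25 (below the
#' 2.5 cut). Observers absent from the histories get count 0 and rank lowest.
#'
#' @param histories data.frame/data.table with columns `observer_id`,
#'   `species`, `year`.
#' @param observers Optional character vector of observer ids to cover even
#'   when they have no history.
#' @param study_year Only records with `year < study_year` count
#'   (default 2019).
#' @return data.table with `observer_id`, `n_species`, `percentile`.
#' @export
compute_expertise <- function(histories, observers = NULL, study_year = 2019L) {
  h <- data.table::as.data.table(histories)
  if (nrow(h) > 0) {
    stopifnot(all(c("observer_id", "species", "year") %in% names(h)))
    counts <- h[year < study_year,
                .(n_species = data.table::uniqueN(species)), by = observer_id]
  } else {
    counts <- data.table::data.table(observer_id = character(),
                                     n_species = integer())
  }
  all_obs <- unique(c(counts$observer_id, observers))
  tab <- data.table::data.table(observer_id = all_obs)
  tab <- counts[tab, on = "observer_id"]
  tab[is.na(n_species), n_species := 0L]
  n <- nrow(tab)
  tab[, percentile := 100 *
        (vapply(n_species, function(c0) sum(tab$n_species < c0), 0) +
         0.5 * vapply(n_species, function(c0) sum(tab$n_species == c0), 0)) / n]
  tab[]
}

#' Filter checklists by effort and expertise rules
#'
#' A record is retained iff it is complete, its protocol is Traveling or
#' Stationary, a Traveling record's distance is < 3 km, its duration lies
#' strictly between 5 and 300 minutes, and its observer's expertise
#' percentile is >= 2.5. Malformed records (negative duration, missing
#' coordinates) get their own tally category. Each rejected record is counted
#' under the first rule it fails (malformed, incomplete, protocol, distance,
#' duration, expertise); the retained set itself is independent of rule order
#' and of record order.
#'
#' @param records Checklist data.table (see [generate_checklists()]).
#' @param expertise Output of [compute_expertise()]; observers missing from
#'   it are treated as count 0 / percentile 0.
#' @param rules Rule list as from [qc_rules()].
#' @return List with `retained` (data.table, with an `expertise` column
#'   attached) and `tally` (data.table of per-rule rejection counts).
#' @export
filter_checklists <- function(records, expertise, rules = qc_rules()) {
  r <- data.table::as.data.table(records)
  ex <- data.table::as.data.table(expertise)
  r <- ex[, .(observer_id, exp_n_species = n_species,
              exp_percentile = percentile)][r, on = "observer_id"]
  r[is.na(exp_n_species), `:=`(exp_n_species = 0L, exp_percentile = 0)]

  malformed <- !is.finite(r$duration_min) | r$duration_min <= 0 |
    !is.finite(r$lat) | !is.finite(r$lon) | abs(r$lat) > 90 | abs(r$lon) > 180
  incomplete <- !r$complete_flag
  bad_protocol <- !r$protocol %in% rules$protocols
  bad_distance <- r$protocol == "Traveling" &
    !(r$distance_km < rules$max_distance_km)
  bad_duration <- !(r$duration_min > rules$min_duration_min &
                    r$duration_min < rules$max_duration_min)
  bad_expertise <- r$exp_percentile < rules$min_expertise_pct

  reason <- rep(NA_character_, nrow(r))
  for (nm in c("expertise", "duration", "distance", "protocol", "incomplete",
               "malformed")) {
    flag <- switch(nm, malformed = malformed, incomplete = incomplete,
                   protocol = bad_protocol, distance = bad_distance,
                   duration = bad_duration, expertise = bad_expertise)
    reason[flag] <- nm                     # later loop entries take precedence
  }
  tally <- data.table::data.table(rule = c("malformed", "incomplete",
    "protocol", "distance", "duration", "expertise"))
  cnt <- table(factor(reason, levels = tally$rule))
  tally[, rejected := as.integer(cnt)]
  list(retained = r[is.na(reason)], tally = tally)
}

#' Spatiotemporal subsampling key
#'
#' The 24-hour day is split into 12 equal bins (`hour_bin = floor(start/2)`);
#' the subsampling key is (year, day-of-year, hour bin, hex cell).
#'
#' @param records Checklist table with `year`, `doy`, `start_time`, `lat`,
#'   `lon`.
#' @param level Hex resolution level (default 7).
#' @return The table with `hour_bin` and `cell_id` columns added.
#' @export
add_spatiotemporal_key <- function(records, level = 7L) {
  r <- data.table::as.data.table(records)
  r[, hour_bin := pmin(11L, as.integer(floor(start_time / 2)))]
  r[, cell_id := hex_index(lat, lon, level)]
  r[]
}

#' Subsample one checklist per spatiotemporal key
#'
#' For every (year, DOY, hour bin, cell) combination exactly one uniformly
#' random record is retained; output size equals the number of distinct keys.
#' Deterministic given `seed` and independent of input row order (records are
#' canonically ordered by checklist id before sampling).
#'
#' @param records Table carrying `year`, `doy`, `hour_bin`, `cell_id`
#'   (see [add_spatiotemporal_key()]).
#' @param seed Integer seed.
#' @return Subsampled data.table.
#' @export
subsample_checklists <- function(records, seed = 1L) {
  r <- data.table::as.data.table(records)
  stopifnot(all(c("year", "doy", "hour_bin", "cell_id") %in% names(r)))
  data.table::setorder(r, year, doy, hour_bin, cell_id, checklist_id)
  with_seed(seed, {
    keep <- r[, .I[sample.int(.N, 1L)], by = .(year, doy, hour_bin, cell_id)]$V1
  })
  out <- r[sort(keep)]
  out[]
}
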