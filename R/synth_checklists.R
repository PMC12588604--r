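# Synthetic checklist generator emulating citizen-science sampling structure:
# hotspot-biased locations, heterogeneous observer expertise with long-tailed
# historical species counts, effort covariates that deliberately include
# QC-violating records, and detections driven by the species truth.

#' Generate synthetic checklists with observer histories
#'
#' Observer skill is a long-tailed latent: historical distinct-species counts
#' are drawn log-normally and detection probability increases monotonically
#' with the observer's skill percentile. Checklist locations are a mixture of
#' a uniform draw over grid cells and Gaussian kernels around a few hotspot
#' cells, with mixture weight `hotspot_bias / (1 + hotspot_bias)` on the
#' hotspot component (0 gives exactly uniform cell sampling). Effort
#' covariates are drawn from wide ranges so that some records violate the QC
#' rules (distance > 3 km, duration < 5 or > 300 min, incomplete checklists)
#' and the filters are exercised.
#'
#' @param truth A `SpeciesTruthSet`.
#' @param n_observers,n_checklists Positive integers.
#' @param hotspot_bias Non-negative hotspot mixture odds.
#' @param seed Integer seed.
#' @param study_year Year stamped on the generated checklists (default 2019).
#' @return List with data.tables `records` (one row per checklist),
#'   `detections` (long: checklist_id, species_id, count), `observers`
#'   (latent skill), and `histories` (pre-study per-observer detections used
#'   by [compute_expertise()]).
#' @export
generate_checklists <- function(truth, n_observers, n_checklists,
                                hotspot_bias = 1, seed = 1L,
                                study_year = 2019L) {
  stopifnot(inherits(truth, "SpeciesTruthSet"))
  if (n_observers < 1 || n_checklists < 1 || hotspot_bias < 0) {
    stop("need n_observers >= 1, n_checklists >= 1, hotspot_bias >= 0",
         call. = FALSE)
  }
  env <- truth$env
  nlat <- length(env$lat); nlon <- length(env$lon)
  dlat <- env$grid$dlat; dlon <- env$grid$dlon

  with_seed(seed, {
    # observers: long-tailed historical species counts and histories
    n_hist <- pmin(400L, pmax(0L, round(rlnorm(n_observers, 3, 1))))
    obs_id <- sprintf("OBS%04d", seq_len(n_observers))
    pool <- sprintf("HSP%03d", 1:600)
    histories <- data.table::rbindlist(lapply(seq_len(n_observers), function(i) {
      if (n_hist[i] == 0L) return(NULL)
      k <- sample.int(600, min(n_hist[i], 600))
      data.table::data.table(observer_id = obs_id[i], species = pool[k],
                             year = sample(2010:(study_year - 1), length(k),
                                           replace = TRUE))
    }))
    skill_pct <- (rank(n_hist, ties.method = "average") - 0.5) / n_observers
    det_mult <- plogis(-0.5 + 3 * skill_pct)        # monotone in percentile
    observers <- data.table::data.table(observer_id = obs_id,
                                        hist_species = n_hist,
                                        skill_pct = skill_pct,
                                        det_mult = det_mult)

    # locations: uniform over cells vs hotspot kernels
    n_hot <- 8L
    hot_i <- sample.int(nlat, n_hot, replace = TRUE)
    hot_j <- sample.int(nlon, n_hot, replace = TRUE)
    p_hot <- hotspot_bias / (1 + hotspot_bias)
    from_hot <- runif(n_checklists) < p_hot
    ci <- integer(n_checklists); cj <- integer(n_checklists)
    n_u <- sum(!from_hot)
    ci[!from_hot] <- sample.int(nlat, n_u, replace = TRUE)
    cj[!from_hot] <- sample.int(nlon, n_u, replace = TRUE)
    if (any(from_hot)) {
      h <- sample.int(n_hot, sum(from_hot), replace = TRUE)
      ci[from_hot] <- pmax(1L, pmin(nlat, hot_i[h] +
        as.integer(round(rnorm(sum(from_hot), 0, 0.7)))))
      cj[from_hot] <- pmax(1L, pmin(nlon, hot_j[h] +
        as.integer(round(rnorm(sum(from_hot), 0, 0.7)))))
    }
    lat <- env$lat[ci] + runif(n_checklists, -dlat / 2, dlat / 2)
    lon <- env$lon[cj] + runif(n_checklists, -dlon / 2, dlon / 2)

    protocol <- sample(c("Traveling", "Stationary", "Other"), n_checklists,
                       replace = TRUE, prob = c(0.70, 0.25, 0.05))
    duration <- clamp(rlnorm(n_checklists, log(60), 0.8), 1, 400)
    distance <- ifelse(protocol == "Traveling",
                       rlnorm(n_checklists, log(1.2), 0.8), 0)
    oi <- sample.int(n_observers, n_checklists, replace = TRUE)
    doy <- sample.int(365, n_checklists, replace = TRUE)
    records <- data.table::data.table(
      checklist_id = sprintf("CL%07d", seq_len(n_checklists)),
      observer_id = obs_id[oi],
      protocol = protocol,
      complete_flag = runif(n_checklists) < 0.9,
      lat = lat, lon = lon,
      year = study_year, doy = doy,
      start_time = runif(n_checklists, 0, 24),
      duration_min = duration,
      distance_km = distance,
      n_observers = 1L + rpois(n_checklists, 0.8)
    )

    # detections from weekly occupancy x detectability x observer skill
    week <- pmin(52L, as.integer(ceiling(doy / 7)))
    det_list <- vector("list", nrow(truth$species))
    for (s in seq_len(nrow(truth$species))) {
      spid <- truth$species$species_id[s]
      occ <- truth$occupancy[[spid]]
      present <- occ[cbind(ci, cj, week)]
      p <- present * truth$species$detectability[s] * det_mult[oi]
      hit <- runif(n_checklists) < p
      if (any(hit)) {
        det_list[[s]] <- data.table::data.table(
          checklist_id = records$checklist_id[hit],
          species_id = spid,
          count = 1L + rpois(sum(hit), 1.2))
      }
    }
    detections <- data.table::rbindlist(det_list)
    list(records = records, detections = detections,
         observers = observers, histories = histories)
  })
}
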