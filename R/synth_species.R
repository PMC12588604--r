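# Synthetic species truth: Gaussian environmental response curves with
# seasonal migration driven by the seasonally varying temperature and
# precipitation fields.

# Mid-DOY of each month (non-leap year).
MONTH_DAYS <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
MONTH_MIDS <- cumsum(MONTH_DAYS) - MONTH_DAYS / 2

week_mid_doy <- function(week) (week - 0.5) * 365 / 52

# Periodic linear interpolation of a monthly stack (nlat x nlon x 12) to a
# given DOY.
monthly_at_doy <- function(stack, doy) {
  mids <- MONTH_MIDS
  doy <- ((doy - 1) %% 365) + 1
  if (doy < mids[1]) {
    m1 <- 12L; m2 <- 1L
    a <- (doy + 365 - mids[12]) / (mids[1] + 365 - mids[12])
  } else if (doy >= mids[12]) {
    m1 <- 12L; m2 <- 1L
    a <- (doy - mids[12]) / (mids[1] + 365 - mids[12])
  } else {
    m1 <- max(which(mids <= doy)); m2 <- m1 + 1L
    a <- (doy - mids[m1]) / (mids[m2] - mids[m1])
  }
  (1 - a) * stack[, , m1] + a * stack[, , m2]
}

# Weekly temperature / precipitation stacks (nlat x nlon x 52).
env_weekly <- function(env) {
  nlat <- length(env$lat); nlon <- length(env$lon)
  temp <- prec <- array(0, c(nlat, nlon, 52))
  for (w in 1:52) {
    d <- week_mid_doy(w)
    temp[, , w] <- monthly_at_doy(env$layers$temperature, d)
    prec[, , w] <- monthly_at_doy(env$layers$precipitation, d)
  }
  list(temperature = temp, precipitation = prec)
}

#' Gaussian suitability
#'
#' Product of Gaussian responses in temperature and precipitation; equals 1 at
#' the joint optimum and exp(-1/2) of the peak one breadth away on one axis.
#'
#' @param sp A single species-truth record (list with `t_opt`, `t_breadth`,
#'   `p_opt`, `p_breadth`).
#' @param temperature,precipitation Environment values (vectors/matrices).
#' @return Suitability in \[0, 1\].
#' @export
suitability <- function(sp, temperature, precipitation) {
  exp(-0.5 * ((temperature - sp$t_opt) / sp$t_breadth)^2) *
    exp(-0.5 * ((precipitation - sp$p_opt) / sp$p_breadth)^2)
}

#' Generate synthetic species truth and weekly occupancy maps
#'
#' Each species gets a Gaussian suitability optimum/breadth for temperature
#' and precipitation, a `seasonal_shift` in \[0, 1\] scaling how strongly its
#' effective environment tracks the weekly (vs annual-mean) fields -- 1 gives
#' a full migrant, 0 a resident with constant weekly occupancy -- and a
#' baseline per-checklist detectability. Weekly occupancy is suitability of
#' that week's (blended) environment thresholded at `threshold`.
#'
#' @param env An `EnvironmentStack`.
#' @param n_species Number of species (>= 1).
#' @param seed Integer seed.
#' @param threshold Occupancy threshold on suitability (default 0.5).
#' @param seasonal_shift Either a single value recycled to all species or a
#'   vector of per-species values in \[0, 1\].
#' @return A `SpeciesTruthSet`: `species` (data.table of response parameters),
#'   `suitability` and `occupancy` (lists of nlat x nlon x 52 arrays), the
#'   `threshold`, and the generating `env`.
#' @export
generate_species_truth <- function(env, n_species, seed, threshold = 0.5,
                                   seasonal_shift = 1) {
  stopifnot(inherits(env, "EnvironmentStack"))
  if (!is.numeric(n_species) || n_species < 1) {
    stop("`n_species` must be >= 1", call. = FALSE)
  }
  n_species <- as.integer(n_species)
  shifts <- rep_len(seasonal_shift, n_species)
  wk <- env_weekly(env)
  t_bar <- apply(wk$temperature, c(1, 2), mean)
  p_bar <- apply(wk$precipitation, c(1, 2), mean)

  with_seed(seed, {
    tq <- quantile(t_bar, c(0.25, 0.8))
    # precipitation optima anchored to the wet end of the weekly field, so
    # monsoon-fed rain belts are the prime habitat
    pq <- quantile(wk$precipitation, c(0.90, 0.97))
    species <- data.table::data.table(
      species_id = sprintf("SP%02d", seq_len(n_species)),
      t_opt = runif(n_species, tq[1], tq[2]),
      t_breadth = runif(n_species, 4, 7),
      p_opt = runif(n_species, pq[1], pq[2]),
      p_breadth = runif(n_species, 0.08, 0.15) *
        diff(range(wk$precipitation)),
      seasonal_shift = shifts,
      detectability = runif(n_species, 0.5, 0.9)
    )
    suit <- occ <- vector("list", n_species)
    names(suit) <- names(occ) <- species$species_id
    for (i in seq_len(n_species)) {
      sp <- as.list(species[i])
      s <- sp$seasonal_shift
      arr <- array(0, dim(wk$temperature))
      for (w in 1:52) {
        t_eff <- t_bar + s * (wk$temperature[, , w] - t_bar)
        p_eff <- p_bar + s * (wk$precipitation[, , w] - p_bar)
        arr[, , w] <- suitability(sp, t_eff, p_eff)
      }
      suit[[i]] <- arr
      occ[[i]] <- arr >= threshold
    }
    structure(list(species = species, suitability = suit, occupancy = occ,
                   threshold = threshold, env = env, seed = as.integer(seed)),
              class = "SpeciesTruthSet")
  })
}

#' @exportS3Method base::print
print.SpeciesTruthSet <- function(x, ...) {
  cat(sprintf("<SpeciesTruthSet> %d species on a %d x %d grid ('%s')\n",
              nrow(x$species), length(x$env$lat), length(x$env$lon),
              x$env$scenario))
  invisible(x)
}

# Weekly abundance-weighted centroid track of a species' suitability surface.
truth_centroid_track <- function(truth, species_id) {
  arr <- truth$suitability[[species_id]]
  env <- truth$env
  lat_m <- matrix(env$lat, length(env$lat), length(env$lon))
  lon_m <- matrix(env$lon, length(env$lat), length(env$lon), byrow = TRUE)
  out <- matrix(NA_real_, 52, 2, dimnames = list(NULL, c("lat", "lon")))
  for (w in 1:52) {
    out[w, ] <- spherical_centroid(as.vector(lat_m), as.vector(lon_m),
                                   as.vector(arr[, , w]))
  }
  data.table::data.table(week = 1:52, lat = out[, 1], lon = out[, 2])
}
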