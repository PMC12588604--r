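# Sampling-effort and temporal features (6 + 2 columns).

EFFORT_COLS <- c("effort_is_traveling", "effort_is_stationary",
                 "effort_distance_km", "effort_duration_min",
                 "effort_n_observers", "effort_expertise")
TEMPORAL_COLS <- c("temporal_doy", "temporal_start_time")

#' Effort and temporal features of one checklist
#'
#' Six effort columns (protocol one-hot over Traveling/Stationary, distance,
#' duration, party size, observer expertise) and two temporal columns (day of
#' year, start time). Records are assumed to have passed QC, so the protocol
#' domain is guaranteed.
#'
#' @param record One-row list/data.frame with `protocol`, `distance_km`,
#'   `duration_min`, `n_observers`, `exp_n_species` (or `expertise`), `doy`,
#'   `start_time`.
#' @return Named numeric vector of length 8.
#' @export
effort_temporal_features <- function(record) {
  r <- as.list(record)
  if (!r$protocol %in% c("Traveling", "Stationary")) {
    stop("internal error: protocol outside QC-guaranteed domain", call. = FALSE)
  }
  expertise <- r$exp_n_species %||% r$expertise
  out <- c(as.numeric(r$protocol == "Traveling"),
           as.numeric(r$protocol == "Stationary"),
           r$distance_km, r$duration_min, r$n_observers, expertise,
           r$doy, r$start_time)
  names(out) <- c(EFFORT_COLS, TEMPORAL_COLS)
  out
}
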