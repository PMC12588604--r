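# Assembly of the canonical 106-column predictor matrix
# (6 effort + 2 temporal + 8 topographic + 19 bioclim + 65 land cover +
#  6 NDVI), with per-family toggles. Column names and order are fixed and
# platform-independent.

#' Feature-family toggles
#' @param effort,temporal,topographic,bioclim,land_cover,ndvi Logical flags.
#' @return Named logical list.
#' @export
feature_toggles <- function(effort = TRUE, temporal = TRUE,
                            topographic = TRUE, bioclim = TRUE,
                            land_cover = TRUE, ndvi = TRUE) {
  list(effort = effort, temporal = temporal, topographic = topographic,
       bioclim = bioclim, land_cover = land_cover, ndvi = ndvi)
}

#' Feature schema
#'
#' @param toggles Output of [feature_toggles()].
#' @return Character vector of column names in canonical order (106 when all
#'   families are enabled), with a `families` attribute mapping each column
#'   to its family.
#' @export
feature_schema <- function(toggles = feature_toggles()) {
  fams <- list(effort = EFFORT_COLS, temporal = TEMPORAL_COLS,
               topographic = TOPO_COLS, bioclim = BIOCLIM_COLS,
               land_cover = LC_COLS, ndvi = NDVI_COLS)
  keep <- fams[unlist(toggles[names(fams)])]
  cols <- unlist(keep, use.names = FALSE)
  attr(cols, "families") <- rep(names(keep), lengths(keep))
  cols
}

#' Assemble the predictor matrix for a set of checklists
#'
#' Effort/temporal features come from the record itself; topographic and
#' land-cover features are computed on deterministic local 1-km patches
#' around each record; bioclim features use the daily series interpolated
#' from the record's grid cell's monthly climate (cached per cell); NDVI
#' features are computed per level-5 hex from the cell's vegetation-index
#' series (cached per hex). Records for which any enabled family fails are
#' dropped with a log entry.
#'
#' @param records QC-passed checklist table (needs `lat`, `lon`, `doy`,
#'   `start_time`, `protocol`, `distance_km`, `duration_min`, `n_observers`,
#'   `exp_n_species`).
#' @param env An `EnvironmentStack` providing the feature layers.
#' @param toggles Family toggles from [feature_toggles()].
#' @return data.table with `checklist_id` plus the schema columns; the
#'   schema (with family attribute) is attached as attribute `"schema"`.
#' @export
assemble_design_matrix <- function(records, env, toggles = feature_toggles()) {
  r <- data.table::as.data.table(records)
  cols <- feature_schema(toggles)
  if (nrow(r) == 0L) {
    empty <- data.table::as.data.table(
      c(list(checklist_id = character()),
        setNames(rep(list(numeric()), length(cols)), cols)))
    attr(empty, "schema") <- cols
    return(empty)
  }

  ij <- env_cell(env, r$lat, r$lon)
  cell_key <- paste(ij[, 1], ij[, 2])
  bio_cache <- new.env(parent = emptyenv())
  ndvi_cache <- new.env(parent = emptyenv())
  hex5 <- hex_index(r$lat, r$lon, 5L)

  n <- nrow(r)
  rows <- vector("list", n)
  dropped <- 0L
  for (k in seq_len(n)) {
    row <- tryCatch({
      parts <- list()
      if (toggles$effort || toggles$temporal) {
        et <- effort_temporal_features(r[k])
        if (toggles$effort) parts$effort <- et[EFFORT_COLS]
        if (toggles$temporal) parts$temporal <- et[TEMPORAL_COLS]
      }
      if (toggles$topographic) {
        dem <- local_dem_patch(env, r$lat[k], r$lon[k])
        parts$topographic <- topographic_features(dem, r$lat[k], r$lon[k])
      }
      if (toggles$bioclim) {
        key <- cell_key[k]
        if (is.null(bio_cache[[key]])) {
          i <- ij[k, 1]; j <- ij[k, 2]
          dt <- daily_from_monthly(env$layers$temperature[i, j, ])
          dp <- daily_from_monthly(env$layers$precipitation[i, j, ],
                                   sum_to_daily = TRUE)
          bio_cache[[key]] <- bioclim_features(dt, dp)
        }
        parts$bioclim <- bio_cache[[key]]
      }
      if (toggles$land_cover) {
        lc <- local_lc_patch(env, r$lat[k], r$lon[k])
        parts$land_cover <- landcover_features(lc, r$lat[k], r$lon[k])
      }
      if (toggles$ndvi) {
        key <- hex5[k]
        if (is.null(ndvi_cache[[key]])) {
          cen <- hex_centroid(key)
          ndvi_cache[[key]] <- ndvi_features(ndvi_series_at(env, cen$lat,
                                                            cen$lon))
        }
        parts$ndvi <- ndvi_cache[[key]]
      }
      unlist(parts, use.names = FALSE)
    }, error = function(e) NULL)
    if (is.null(row)) dropped <- dropped + 1L
    rows[[k]] <- row
  }
  ok <- !vapply(rows, is.null, TRUE)
  if (dropped > 0L) {
    message(sprintf("assemble_design_matrix: dropped %d record(s) with failed features",
                    dropped))
  }
  mat <- do.call(rbind, rows[ok])
  colnames(mat) <- cols
  out <- data.table::data.table(checklist_id = r$checklist_id[ok])
  out <- cbind(out, data.table::as.data.table(mat))
  attr(out, "schema") <- cols
  out
}
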