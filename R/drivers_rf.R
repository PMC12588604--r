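# Segment annotation with environmental drivers, the random-forest direction
# model, and counterfactual direction prediction.

#' Annotate migration segments with environmental drivers
#'
#' Each driver (wind cost, vegetation, annual mean temperature, annual
#' precipitation, elevation) is the mean of the layer values at the
#' segment's two endpoint cells. Segments falling outside layer coverage are
#' dropped with a log entry. Standardisation is applied later, within each
#' model's data subset (see [standardize_drivers()]).
#'
#' @param segments `MigrationSegment` table ([build_segments()]).
#' @param env `EnvironmentStack` for the scenario being annotated.
#' @param wind_cost `WindCostLayer` ([wind_cost_layer()]) on the same grid.
#' @return DriverTable: the segments plus raw driver columns.
#' @export
annotate_segments <- function(segments, env, wind_cost) {
  seg <- data.table::as.data.table(segments)
  if (nrow(seg) == 0L) return(seg)
  ann <- env_annual_layers(env)
  nlat <- length(env$lat)
  wc <- data.table::as.data.table(wind_cost)
  wc_m <- matrix(NA_real_, nlat, length(env$lon))
  wc_m[wc$cell] <- wc$wind_cost
  layer_mean <- function(m, seg) {
    ij1 <- env_cell(env, seg$from_lat, seg$from_lon)
    ij2 <- env_cell(env, seg$to_lat, seg$to_lon)
    (m[ij1] + m[ij2]) / 2
  }
  inside <- function(lat, lon) {
    lat >= min(env$lat) - env$grid$dlat & lat <= max(env$lat) + env$grid$dlat &
      lon >= min(env$lon) - env$grid$dlon & lon <= max(env$lon) + env$grid$dlon
  }
  cov <- inside(seg$from_lat, seg$from_lon) & inside(seg$to_lat, seg$to_lon)
  if (any(!cov)) {
    message(sprintf("annotate_segments: dropped %d segment(s) outside coverage",
                    sum(!cov)))
    seg <- seg[cov]
  }
  seg[, wind_cost := layer_mean(wc_m, seg)]
  seg[, vegetation := layer_mean(ann$vegetation, seg)]
  seg[, temperature := layer_mean(ann$temperature, seg)]
  seg[, precipitation := layer_mean(ann$precipitation, seg)]
  seg[, elevation := layer_mean(ann$elevation, seg)]
  ok <- stats::complete.cases(seg[, DRIVER_COLS, with = FALSE])
  if (any(!ok)) {
    message(sprintf("annotate_segments: dropped %d segment(s) with missing drivers",
                    sum(!ok)))
    seg <- seg[ok]
  }
  seg[]
}

#' Random-forest model of migratory direction
#'
#' Tree-ensemble regression of azimuth on the five standardised drivers, with
#' out-of-bag permutation importances. The standardisation constants are
#' stored so counterfactual tables are transformed with the training
#' constants, never refit.
#'
#' @param table DriverTable with raw driver columns and `azimuth`.
#' @param seed Integer seed.
#' @param n_trees,mtry,min_node Forest settings.
#' @return `DirectionRF`: the forest, `importance` (named, decreasing), and
#'   the training standardisation constants.
#' @export
fit_rf <- function(table, seed = 1L, n_trees = 300L, mtry = 2L,
                   min_node = 5L) {
  tab <- data.table::as.data.table(table)
  if (nrow(tab) < 2L) stop("need at least 2 segments", call. = FALSE)
  std <- standardize_drivers(tab)
  X <- as.matrix(std[, DRIVER_COLS, with = FALSE])
  forest <- ww_forest(X, std$azimuth, n_trees = n_trees, mtry = mtry,
                      min_node = min_node, seed = seed)
  structure(list(forest = forest,
                 importance = forest_importance(forest, seed = seed),
                 center = attr(std, "center"), scale = attr(std, "scale")),
            class = "DirectionRF")
}

#' @exportS3Method base::print
print.DirectionRF <- function(x, ...) {
  cat("<DirectionRF> permutation importance (OOB MSE increase):\n")
  print(round(x$importance, 3))
  invisible(x)
}

#' Predict counterfactual migratory directions
#'
#' Applies the training-set standardisation constants to the counterfactual
#' driver table (guarding against standardisation leakage), predicts
#' per-segment azimuths, and summarises modern vs counterfactual direction
#' classes and roses.
#'
#' @param model A `DirectionRF`.
#' @param table Counterfactual DriverTable with the raw driver columns.
#' @return List: `azimuth` (predicted, degrees), `direction_class`,
#'   `class_fractions`, `rose` ([direction_rose()] of the predictions).
#' @export
predict_counterfactual_directions <- function(model, table) {
  tab <- data.table::as.data.table(table)
  missing <- setdiff(DRIVER_COLS, names(tab))
  if (length(missing)) {
    stop(sprintf("counterfactual table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  X <- as.matrix(tab[, DRIVER_COLS, with = FALSE])
  X <- sweep(sweep(X, 2, model$center[DRIVER_COLS]), 2,
             model$scale[DRIVER_COLS], "/")
  az <- wrap360(predict(model$forest, X))
  cls <- direction_class(az)
  list(azimuth = az, direction_class = cls,
       class_fractions = prop.table(base::table(factor(cls,
         levels = c("latitudinal", "longitudinal")))),
       rose = direction_rose(az))
}
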