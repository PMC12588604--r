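# Plain-text IO: gridded layers as long-form CSV (no NetCDF/GeoTIFF-capable
# R package is available in this stack; the CSV carries the same information
# with a JSON sidecar), checklists/segments/posteriors as CSV, routes as
# GeoJSON, config as YAML.

#' Write an environment stack to long-form CSV
#'
#' One row per (layer, slice, lat, lon); monthly layers use slice 1-12, the
#' NDVI stack its 16-day DOYs, static layers slice NA. A JSON sidecar stores
#' scenario, seed and grid metadata.
#'
#' @param env `EnvironmentStack`.
#' @param path Output CSV path (sidecar gets extension `.json`).
#' @return `path`, invisibly.
#' @export
write_env_stack <- function(env, path) {
  rows <- list()
  lat_m <- matrix(env$lat, length(env$lat), length(env$lon))
  lon_m <- matrix(env$lon, length(env$lat), length(env$lon), byrow = TRUE)
  add <- function(layer, slice, m) {
    rows[[length(rows) + 1L]] <<- data.table::data.table(
      layer = layer, slice = slice, lat = as.vector(lat_m),
      lon = as.vector(lon_m), value = as.vector(m))
  }
  for (nm in names(env$layers)) {
    z <- env$layers[[nm]]
    if (length(dim(z)) == 3L) {
      slices <- if (nm == "ndvi") env$params$ndvi_doys else seq_len(dim(z)[3])
      for (k in seq_len(dim(z)[3])) add(nm, slices[k], z[, , k])
    } else add(nm, NA_integer_, z)
  }
  out <- data.table::rbindlist(rows)
  data.table::fwrite(out, path)
  meta <- list(scenario = env$scenario, seed = env$seed,
               grid = env$grid[c("lat_min", "lat_max", "lon_min", "lon_max",
                                 "dlat", "dlon")])
  jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an environment stack written by [write_env_stack()]
#' @param path CSV path.
#' @return `EnvironmentStack` (regenerated arrays; parameters from sidecar).
#' @export
read_env_stack <- function(path) {
  tab <- data.table::fread(path)
  meta <- jsonlite::read_json(paste0(tools::file_path_sans_ext(path), ".json"),
                              simplifyVector = TRUE)
  g <- do.call(grid_spec, meta$grid)
  nlat <- length(g$lat); nlon <- length(g$lon)
  layers <- list()
  for (nm in unique(tab$layer)) {
    sub <- tab[layer == nm]
    slices <- sort(unique(sub$slice))
    if (all(is.na(slices)) || length(slices) == 0L) {
      m <- matrix(NA_real_, nlat, nlon)
      ij <- raster_cell(list(lat = g$lat, lon = g$lon), sub$lat, sub$lon)
      m[cbind(ij[, 1], ij[, 2])] <- sub$value
      layers[[nm]] <- if (nm == "land_cover") {
        mm <- m; storage.mode(mm) <- "integer"; mm
      } else m
    } else {
      a <- array(NA_real_, c(nlat, nlon, length(slices)))
      for (k in seq_along(slices)) {
        sl <- sub[slice == slices[k]]
        ij <- raster_cell(list(lat = g$lat, lon = g$lon), sl$lat, sl$lon)
        a[cbind(ij[, 1], ij[, 2], k)] <- sl$value
      }
      layers[[nm]] <- a
    }
  }
  params <- env_params()
  if ("ndvi" %in% names(layers)) {
    params$ndvi_doys <- sort(unique(tab[layer == "ndvi"]$slice))
  }
  structure(list(scenario = meta$scenario, lat = g$lat, lon = g$lon, grid = g,
                 params = params, seed = as.integer(meta$seed),
                 layers = layers), class = "EnvironmentStack")
}

#' Write routes as GeoJSON LineStrings
#'
#' @param tracks Output of [generate_tracks()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tracks_geojson <- function(tracks, path) {
  tr <- data.table::as.data.table(tracks)
  feats <- lapply(split(tr, tr$individual_id), function(d) {
    d <- d[order(d$order)]
    list(type = "Feature",
         properties = list(individual_id = d$individual_id[1],
                           species_id = d$species_id[1],
                           migratory = d$migratory[1],
                           labels = d$label, weeks = d$week),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(d)), function(i)
                           c(d$lon[i], d$lat[i]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection",
                            features = unname(feats)),
                       path, auto_unbox = TRUE, digits = 8)
  invisible(path)
}

#' Load and validate a pipeline configuration
#'
#' YAML file holding generator parameters and seeds; unknown keys are
#' rejected before any stage runs, missing keys take defaults.
#'
#' @param path YAML path, or NULL for the defaults.
#' @return Full config list.
#' @export
load_config <- function(path = NULL) {
  defaults <- default_config()
  if (is.null(path)) return(defaults)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  utils::modifyList(defaults, user)
}
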