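# Hexagonal spatial indexing.
#
# No H3 binding is available to R in this stack, so this is a documented
# fallback: a pointy-top axial hex lattice laid out on the sinusoidal
# equal-area projection (x = K * lon * cos(lat), y = K * lat, K = pi*R/180 km
# per degree). Because the projection is area-preserving, plane-equal-area
# hexagons are (to projection accuracy) equal-area on the sphere. Cells are
# deterministic and tile the projected plane without overlap, which is the
# contract downstream code relies on; the H3 bit layout is not emulated.
#
# Level scaling follows the aperture-7 convention: the level-7 cell area is
# 5.161293 km^2 (matching H3's published resolution-7 average) and each
# coarser level multiplies the area by 7.

KM_PER_DEG <- EARTH_RADIUS_KM * pi / 180

hex_edge_km <- function(level) {
  area7 <- 5.161293
  area <- area7 * 7^(7 - level)
  sqrt(2 * area / (3 * sqrt(3)))
}

hex_project <- function(lat, lon) {
  cbind(x = KM_PER_DEG * lon * cos(deg2rad(lat)), y = KM_PER_DEG * lat)
}

hex_unproject <- function(x, y) {
  lat <- y / KM_PER_DEG
  lon <- x / (KM_PER_DEG * cos(deg2rad(lat)))
  cbind(lat = lat, lon = lon)
}

# Cube-coordinate rounding of fractional axial coords (qf, rf).
hex_round <- function(qf, rf) {
  xf <- qf; zf <- rf; yf <- -xf - zf
  rx <- round(xf); ry <- round(yf); rz <- round(zf)
  dx <- abs(rx - xf); dy <- abs(ry - yf); dz <- abs(rz - zf)
  fix_x <- dx > dy & dx > dz
  fix_z <- !fix_x & dz > dy
  rx[fix_x] <- -ry[fix_x] - rz[fix_x]
  rz[fix_z] <- -rx[fix_z] - ry[fix_z]
  cbind(q = as.integer(rx), r = as.integer(rz))
}

#' Hexagonal cell index of a point
#'
#' Assigns coordinates to a deterministic, non-overlapping hexagonal cell at
#' the given resolution level (default 7, cell area ~5.16 km^2). Same
#' (lat, lon, level) always yields the same id.
#'
#' @param lat,lon Coordinates in degrees (vectors allowed).
#' @param level Integer resolution level (0-15); level 7 is the default
#'   checklist-subsampling resolution.
#' @return Character vector of cell ids of the form `"H<level>:<q>:<r>"`.
#' @export
hex_index <- function(lat, lon, level = 7L) {
  if (any(!is.finite(lat)) || any(!is.finite(lon)) ||
      any(abs(lat) > 90) || any(abs(lon) > 180)) {
    stop("invalid coordinates: need |lat| <= 90 and |lon| <= 180", call. = FALSE)
  }
  if (length(level) != 1L || level < 0 || level > 15) {
    stop("`level` must be a single integer in 0..15", call. = FALSE)
  }
  a <- hex_edge_km(level)
  p <- hex_project(lat, lon)
  qf <- (sqrt(3) / 3 * p[, "x"] - 1 / 3 * p[, "y"]) / a
  rf <- (2 / 3 * p[, "y"]) / a
  qr <- hex_round(qf, rf)
  sprintf("H%d:%d:%d", as.integer(level), qr[, "q"], qr[, "r"])
}

#' Centroid of a hexagonal cell
#'
#' @param cell_id Ids produced by [hex_index()].
#' @return Data frame with columns `lat`, `lon`.
#' @export
hex_centroid <- function(cell_id) {
  parts <- do.call(rbind, strsplit(sub("^H", "", cell_id), ":", fixed = TRUE))
  level <- as.integer(parts[, 1]); q <- as.numeric(parts[, 2])
  r <- as.numeric(parts[, 3])
  a <- hex_edge_km(level)
  x <- a * sqrt(3) * (q + r / 2)
  y <- a * 3 / 2 * r
  as.data.frame(hex_unproject(x, y))
}

#' Parent cell at a coarser level
#'
#' Defined as the coarser-level index of the child cell's centroid. With this
#' fallback lattice the parent is not guaranteed to strictly contain the whole
#' child polygon (hexagons do not nest), but typical points re-index stably.
#'
#' @param cell_id Child cell ids.
#' @param parent_level Coarser level (must be < child level).
#' @return Parent cell ids.
#' @export
hex_parent <- function(cell_id, parent_level) {
  cen <- hex_centroid(cell_id)
  hex_index(cen$lat, cen$lon, parent_level)
}
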