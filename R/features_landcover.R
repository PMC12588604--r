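# Land-cover landscape metrics (65 columns): for each of 10 canonical classes
# the 6 per-class metrics (percentage cover, patch density, largest patch
# index, edge density, mean patch size, sd of patch size; 4-connectivity
# patches, densities per unit buffer area), plus 5 buffer-level metrics
# (entropy of class composition in nats, total patch density, overall largest
# patch index, overall edge density, overall mean patch size).

LC_CLASSES <- 1:10
LC_METRICS <- c("pct_cover", "patch_density", "largest_patch_index",
                "edge_density", "mean_patch_km2", "sd_patch_km2")
LC_COLS <- c(as.vector(t(outer(sprintf("lc_c%02d", LC_CLASSES), LC_METRICS,
                               paste, sep = "_"))),
             "lc_entropy", "lc_total_patch_density",
             "lc_overall_largest_patch_index", "lc_overall_edge_density",
             "lc_overall_mean_patch_km2")

# 4-connected component labelling of a class mask (small matrices; BFS).
label_patches <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  lab <- matrix(0L, n, m); cur <- 0L
  for (s in which(mask)) {
    if (lab[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      cell <- queue[[1]]; queue <- queue[-1]
      i <- ((cell - 1L) %% n) + 1L; j <- ((cell - 1L) %/% n) + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1L && ii <= n && jj >= 1L && jj <= m) {
          nb <- (jj - 1L) * n + ii
          if (mask[nb] && lab[nb] == 0L) {
            lab[nb] <- cur
            queue <- c(queue, nb)
          }
        }
      }
    }
  }
  list(labels = lab, n = cur)
}

# Count 4-adjacent cell pairs (a, b) with cls[a] == k and cls[b] != k (per
# class), and pairs with differing classes (overall, each pair once).
edge_counts <- function(cls, classes) {
  n <- nrow(cls); m <- ncol(cls)
  per <- setNames(numeric(length(classes)), classes)
  overall <- 0
  pair_add <- function(a, b) {
    diffm <- a != b
    overall <<- overall + sum(diffm)
    for (k in classes) {
      per[as.character(k)] <<- per[as.character(k)] +
        sum(diffm & (a == k)) + sum(diffm & (b == k))
    }
  }
  if (n > 1) pair_add(cls[-n, , drop = FALSE], cls[-1, , drop = FALSE])
  if (m > 1) pair_add(cls[, -m, drop = FALSE], cls[, -1, drop = FALSE])
  list(per_class = per, overall = overall)
}

#' Land-cover landscape features over a buffered area
#'
#' @param lc A `ww_raster` of integer class ids covering the buffer.
#' @param lat,lon Point coordinates (degrees).
#' @param buffer_km Buffer side length (default 3).
#' @param cell_km Cell side length in km used for areas/edge lengths
#'   (default 1).
#' @param classes Canonical class legend (default 1:10); absent classes yield
#'   zero columns.
#' @return Named numeric vector of length 65.
#' @export
landcover_features <- function(lc, lat, lon, buffer_km = 3, cell_km = 1,
                               classes = LC_CLASSES) {
  half_lat <- (buffer_km / 2) / KM_PER_DEG
  half_lon <- (buffer_km / 2) / (KM_PER_DEG * cos(deg2rad(lat)))
  sel_i <- which(abs(lc$lat - lat) <= half_lat + 1e-9)
  sel_j <- which(abs(lc$lon - lon) <= half_lon + 1e-9)
  if (length(sel_i) == 0L || length(sel_j) == 0L) {
    stop("empty land-cover buffer", call. = FALSE)
  }
  cls <- lc$z[sel_i, sel_j, drop = FALSE]
  landcover_metrics(cls, cell_km = cell_km, classes = classes)
}

# Metrics on a class matrix directly (exposed for oracle tests).
landcover_metrics <- function(cls, cell_km = 1, classes = LC_CLASSES) {
  n_cells <- length(cls)
  area_buf <- n_cells * cell_km^2
  cell_area <- cell_km^2
  ec <- edge_counts(cls, classes)
  out <- numeric(0)
  all_patch_areas <- numeric(0)
  total_patches <- 0L
  for (k in classes) {
    mask <- cls == k
    nk <- sum(mask)
    if (nk == 0L) {
      vals <- numeric(6)
    } else {
      lp <- label_patches(mask)
      sizes <- tabulate(lp$labels[lp$labels > 0L], nbins = lp$n) * cell_area
      all_patch_areas <- c(all_patch_areas, sizes)
      total_patches <- total_patches + lp$n
      vals <- c(100 * nk / n_cells,
                lp$n / area_buf,
                100 * max(sizes) / area_buf,
                ec$per_class[as.character(k)] * cell_km / area_buf,
                mean(sizes),
                if (length(sizes) > 1) sd(sizes) else 0)
    }
    out <- c(out, vals)
  }
  p <- tabulate(factor(cls, levels = classes), nbins = length(classes)) / n_cells
  p <- p[p > 0]
  entropy <- -sum(p * log(p))
  out <- c(out, entropy,
           total_patches / area_buf,
           if (length(all_patch_areas)) 100 * max(all_patch_areas) / area_buf else 0,
           ec$overall * cell_km / area_buf,
           if (length(all_patch_areas)) mean(all_patch_areas) else 0)
  names(out) <- LC_COLS
  out
}
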