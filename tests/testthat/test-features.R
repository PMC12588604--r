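# feature_engineering: effort/temporal, topographic, land cover, bioclim,
# NDVI, and assembly of the 106-column matrix.

test_that("effort and temporal features echo the record", {
  r <- data.frame(protocol = "Traveling", distance_km = 2.5,
                  duration_min = 30, n_observers = 2, exp_n_species = 120,
                  doy = 140, start_time = 6.5)
  f <- effort_temporal_features(r)
  expect_equal(unname(f), c(1, 0, 2.5, 30, 2, 120, 140, 6.5))
  s <- r; s$protocol <- "Stationary"; s$distance_km <- 0
  fs <- effort_temporal_features(s)
  expect_equal(unname(fs[1:3]), c(0, 1, 0))
  expect_identical(f, effort_temporal_features(r))
  bad <- r; bad$protocol <- "Other"
  expect_error(effort_temporal_features(bad), "internal error")
})

test_that("topographic features are exact on analytic surfaces", {
  # flat DEM: means (500, 0, 0, 0), all sds 0
  flat <- topographic_features(plane_dem(), 20, 100)
  expect_equal(unname(flat),
               c(500, 0, 0, 0, 0, 0, 0, 0), tolerance = 1e-10)
  # plane rising due north at 0.1 m/m: slope atan(0.1), aspect south ->
  # northness -1, eastness 0, all sds 0
  north <- topographic_features(plane_dem(slope_north = 0.1), 20, 100)
  expect_equal(unname(north["topo_slope_mean"]), atan(0.1), tolerance = 1e-6)
  expect_equal(unname(north["topo_north_mean"]), -1, tolerance = 1e-6)
  expect_equal(unname(north["topo_east_mean"]), 0, tolerance = 1e-6)
  expect_equal(unname(north["topo_slope_sd"]), 0, tolerance = 1e-9)
  # plane rising due east: downhill west -> eastness -1
  east <- topographic_features(plane_dem(slope_east = 0.05), 20, 100)
  expect_equal(unname(east["topo_east_mean"]), -1, tolerance = 1e-6)
  # single-cell buffer: sds exactly 0
  one <- topographic_features(plane_dem(slope_north = 0.1), 20, 100,
                              buffer_km = 0.9)
  expect_equal(unname(one["topo_elev_sd"]), 0)
})

# Brute-force landscape oracle: igraph connected components on the lattice.
oracle_landcover <- function(cls, cell_km = 1, classes = 1:10) {
  n <- nrow(cls); m <- ncol(cls)
  idx <- function(i, j) (j - 1) * n + i
  edges <- NULL
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (i < n && cls[i, j] == cls[i + 1, j]) {
      edges <- rbind(edges, c(idx(i, j), idx(i + 1, j)))
    }
    if (j < m && cls[i, j] == cls[i, j + 1]) {
      edges <- rbind(edges, c(idx(i, j), idx(i, j + 1)))
    }
  }
  g <- igraph::graph_from_edgelist(if (is.null(edges))
    matrix(0L, 0, 2) else edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n * m - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  area <- n * m * cell_km^2
  out <- c()
  patch_all <- c(); tot_patches <- 0
  # per-class edge pairs
  diff_v <- cls[-n, , drop = FALSE] != cls[-1, , drop = FALSE]
  diff_h <- cls[, -m, drop = FALSE] != cls[, -1, drop = FALSE]
  for (k in classes) {
    cells <- which(as.vector(cls) == k)
    if (!length(cells)) { out <- c(out, numeric(6)); next }
    sizes <- as.vector(table(comp[cells])) * cell_km^2
    patch_all <- c(patch_all, sizes); tot_patches <- tot_patches + length(sizes)
    per_edges <- sum(diff_v & (cls[-n, ] == k | cls[-1, ] == k)) +
      sum(diff_h & (cls[, -m] == k | cls[, -1] == k))
    out <- c(out, 100 * length(cells) / (n * m), length(sizes) / area,
             100 * max(sizes) / area, per_edges * cell_km / area,
             mean(sizes), if (length(sizes) > 1) sd(sizes) else 0)
  }
  p <- as.vector(table(factor(cls, levels = classes))) / (n * m)
  p <- p[p > 0]
  c(out, -sum(p * log(p)), tot_patches / area,
    100 * max(patch_all) / area, (sum(diff_v) + sum(diff_h)) * cell_km / area,
    mean(patch_all))
}

test_that("landscape metrics match closed forms and the brute-force oracle", {
  # homogeneous buffer
  hom <- windward:::landcover_metrics(matrix(3L, 4, 4))
  expect_equal(unname(hom["lc_c03_pct_cover"]), 100)
  expect_equal(unname(hom["lc_entropy"]), 0)
  expect_equal(unname(hom["lc_c03_edge_density"]), 0)
  expect_equal(unname(hom["lc_c03_patch_density"]), 1 / 16)
  # two classes split by a straight boundary: entropy ln 2, 50% cover each
  half <- windward:::landcover_metrics(
    matrix(c(1L, 1L, 2L, 2L)[rep(1:4, each = 4)], 4, 4, byrow = TRUE))
  expect_equal(unname(half["lc_entropy"]), log(2))
  expect_equal(unname(half["lc_c01_pct_cover"]), 50)
  expect_equal(unname(half["lc_c02_pct_cover"]), 50)
  # checkerboard and random rasters vs oracle, all rasters <= 8x8
  set.seed(42)
  cases <- c(
    list(matrix(rep(c(1L, 2L), 8), 4, 4)),                   # checkerboard
    lapply(1:20, function(k) matrix(sample(1:4, 36, TRUE), 6, 6)),
    lapply(1:5, function(k) matrix(sample(1:10, 64, TRUE), 8, 8)))
  for (cls in cases) {
    expect_equal(unname(windward:::landcover_metrics(cls)),
                 unname(oracle_landcover(cls)), tolerance = 1e-12)
  }
})

# Straight-line independent reimplementation of the 19 bioclim summaries.
oracle_bioclim <- function(tt, pp) {
  md <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  mo <- rep(1:12, md)
  tmean <- sapply(1:12, function(m) mean(tt[mo == m]))
  tmax <- sapply(1:12, function(m) max(tt[mo == m]))
  tmin <- sapply(1:12, function(m) min(tt[mo == m]))
  pm <- sapply(1:12, function(m) sum(pp[mo == m]))
  tq <- pq <- numeric(12)
  for (q in 1:12) {
    ms <- ((q - 1):(q + 1) - 1) %% 12 + 1
    tq[q] <- mean(tmean[ms]); pq[q] <- sum(pm[ms])
  }
  b5 <- max(tmax); b6 <- min(tmin); b7 <- b5 - b6
  b2 <- mean(tmax - tmin)
  c(mean(tmean), b2, if (b7 > 0) 100 * b2 / b7 else 0, 100 * sd(tmean),
    b5, b6, b7, tq[which.max(pq)], tq[which.min(pq)], max(tq), min(tq),
    sum(pm), max(pm), min(pm),
    if (mean(pm) > 0) 100 * sd(pm) / mean(pm) else 0,
    max(pq), min(pq), pq[which.max(tq)], pq[which.min(tq)])
}

test_that("bioclim features match constants, identities and the oracle", {
  # constant 10 degC, 100 mm per month (daily rate adjusted per month length)
  md <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  const <- bioclim_features(rep(10, 365), rep(100 / md, md))
  expect_equal(unname(const[c("bio01", "bio04", "bio12", "bio15")]),
               c(10, 0, 1200, 0))
  # identity BIO7 = BIO5 - BIO6 on a sinusoid
  doy <- 1:365
  sinu <- bioclim_features(15 + 10 * sin(2 * pi * (doy - 100) / 365),
                           3 + 2 * cos(2 * pi * doy / 365))
  expect_equal(unname(sinu["bio07"]),
               unname(sinu["bio05"] - sinu["bio06"]))
  # oracle equivalence on 100 random synthetic climates, tolerance 1e-9
  set.seed(7)
  for (k in 1:100) {
    tt <- rnorm(1, 10, 8) + rnorm(1, 8, 3) * sin(2 * pi * (doy - runif(1, 0, 365)) / 365) +
      rnorm(365, 0, 1.5)
    pp <- pmax(0, rnorm(1, 3, 1.5) + rnorm(1, 2, 1) *
                 cos(2 * pi * (doy - runif(1, 0, 365)) / 365) + rnorm(365, 0, 1))
    expect_equal(unname(bioclim_features(tt, pp)), oracle_bioclim(tt, pp),
                 tolerance = 1e-9)
  }
  expect_error(bioclim_features(rep(1, 100), rep(1, 100)), "365")
})

test_that("NDVI phenology features honour the smoother contract", {
  doys <- seq(9, 365, by = 16)
  # constant series
  const <- ndvi_features(data.frame(doy = doys, ndvi = 0.5))
  expect_equal(unname(const), c(0.5, 0.5, 0.5, 0, 0, 0), tolerance = 1e-8)
  # linear series: derivative features equal the slope within 1e-3
  slope <- 0.002
  lin <- ndvi_features(data.frame(doy = doys, ndvi = 0.1 + slope * doys))
  expect_equal(unname(lin[4:6]), rep(slope, 3), tolerance = 1e-3)
  # single-peak curve: order statistics
  peak <- ndvi_features(data.frame(
    doy = doys, ndvi = 0.2 + 0.6 * exp(-((doys - 200) / 60)^2)))
  expect_gte(peak["ndvi_max"], peak["ndvi_median"])
  expect_gte(peak["ndvi_median"], peak["ndvi_min"])
  expect_error(ndvi_features(data.frame(doy = 1:5, ndvi = 0.1)), ">= 8")
})

test_that("design matrix has the canonical 106-column schema", {
  w <- test_world()
  schema <- feature_schema()
  expect_length(schema, 106L)
  fam <- table(attr(schema, "families"))
  expect_equal(as.integer(fam[c("effort", "temporal", "topographic",
                                "bioclim", "land_cover", "ndvi")]),
               c(6L, 2L, 8L, 19L, 65L, 6L))
  # ndvi family off -> 100 columns
  expect_length(feature_schema(feature_toggles(ndvi = FALSE)), 100L)

  ex <- compute_expertise(w$sim$histories,
                          observers = w$sim$observers$observer_id)
  rec <- filter_checklists(w$sim$records, ex)$retained[1:25]
  X <- assemble_design_matrix(rec, w$env_m)
  expect_identical(names(X)[-1], as.character(schema))
  expect_equal(nrow(X), 25L)
  expect_false(anyNA(X))
  # schema stability across runs
  X2 <- assemble_design_matrix(rec, w$env_m)
  expect_identical(X, X2)
  # empty input keeps the full header
  empty <- assemble_design_matrix(rec[0], w$env_m)
  expect_equal(nrow(empty), 0L)
  expect_identical(names(empty)[-1], as.character(schema))
})
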