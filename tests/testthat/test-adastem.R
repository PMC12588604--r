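# adastem: temporal windows, QuadTree, stixel fitting, prediction,
# quantile filter.

test_that("temporal windows cover the year cyclically", {
  w <- temporal_windows(50, 20)
  expect_equal(nrow(w), 19L)
  # DOY 10 lies in the windows starting 1, 341 (wrapped), 361 (wrapped)
  inw <- w$start[windward:::doy_in_window(10, w$start, w$end)]
  expect_setequal(inw, c(1, 341, 361))
  # every DOY covered by >= 2 windows (exhaustive)
  cover <- vapply(1:366, function(d)
    sum(windward:::doy_in_window(d, w$start, w$end)), 0)
  expect_true(all(cover >= 2))
  # degenerate all-year window
  expect_equal(nrow(temporal_windows(366, 366)), 1L)
  expect_error(temporal_windows(10, 20), "step")
})

test_that("quadtree splits by the stated rule and tiles the root", {
  set.seed(3)
  # 40 deg root with 1000 points: root must split (side > 25)
  lon <- runif(1000, 60, 100); lat <- runif(1000, 0, 40)
  leaves <- quadtree_partition(lon, lat, fold_seed = 1)
  expect_gt(nrow(leaves), 1L)
  expect_true(all(leaves$lon1 - leaves$lon0 <= 25 + 1e-9))
  # min side respected
  expect_true(all(leaves$lon1 - leaves$lon0 >= 5 - 1e-9))
  # 8 deg node with 30 points stays a leaf
  l2 <- quadtree_partition(runif(30, 0, 8), runif(30, 0, 8),
                           root = c(0, 0, 8))
  expect_equal(nrow(l2), 1L)
  # partition property: leaves tile the root (area sum, no overlaps)
  side <- leaves$lon1[1] - leaves$lon0[1]
  root_area <- max(leaves$lon1) - min(leaves$lon0)
  expect_equal(sum((leaves$lon1 - leaves$lon0) * (leaves$lat1 - leaves$lat0)),
               (max(leaves$lon1) - min(leaves$lon0)) *
                 (max(leaves$lat1) - min(leaves$lat0)))
  # every training point in exactly one leaf
  loc <- windward:::leaf_locate(leaves, lon, lat)
  expect_false(anyNA(loc))
  expect_equal(sum(leaves$n), 1000L)
  # fold jitter decorrelates: different fold seeds give different origins
  l3 <- quadtree_partition(lon, lat, fold_seed = 2)
  expect_false(isTRUE(all.equal(min(leaves$lon0), min(l3$lon0))))
})

# Dense toy over a 12 x 12 deg block, so QuadTree leaves (>= 5 deg side)
# comfortably hold the 50 checklists a fitted stixel needs.
adastem_toy <- function(n = 600, seed = 4) {
  set.seed(seed)
  data.table::data.table(
    lon = runif(n, 60, 72), lat = runif(n, 0, 12),
    doy = sample.int(365, n, TRUE), x1 = runif(n), x2 = runif(n))
}

test_that("stixel ensemble matches the stratified-mean oracle", {
  tr <- adastem_toy()
  # range-structured response: inside a lon/lat box counts are high
  y <- ifelse(tr$lon > 66 & tr$lat > 6, 4, 0) + rpois(nrow(tr), 0.05)

  cfg <- adastem_config(n_folds = 1L, window = 366L, step = 366L,
                        base = base_learner_mean(), coverage_min = 0L)
  fit <- fit_adastem(tr, y, cfg, seed = 9)
  pred <- predict_adastem(fit, tr, week = 26)
  # oracle: per-leaf group means
  leaves <- fit$folds[[1]][[1]]$leaves
  loc <- windward:::leaf_locate(leaves, tr$lon, tr$lat)
  gm <- tapply(y, loc, mean)
  fitted_leaves <- !vapply(fit$folds[[1]][[1]]$models, is.null, TRUE)
  expect_gt(sum(fitted_leaves), 0L)   # the toy is dense enough to fit
  for (lf in leaves$leaf_id[fitted_leaves]) {
    rows <- which(loc == lf)
    expect_equal(unique(pred$abundance[rows]), unname(gm[as.character(lf)]),
                 tolerance = 1e-12)
  }
  # constant-response data: every fitted stixel predicts the constant
  fitc <- fit_adastem(tr, rep(4, nrow(tr)), cfg, seed = 9)
  pc <- predict_adastem(fitc, tr, week = 26)
  expect_true(all(abs(pc$abundance[pc$coverage > 0] - 4) < 1e-12))
  # determinism
  fit2 <- fit_adastem(tr, y, cfg, seed = 9)
  expect_equal(predict_adastem(fit2, tr, week = 26), pred)
})

test_that("prediction aggregates by median with coverage masking", {
  # hand-built ensemble: constant-classifier folds with known outputs
  vals <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 100)
  cfg <- adastem_config(n_folds = 10L, window = 366L, step = 366L,
                        base = base_learner_mean())
  tr <- adastem_toy(1200)
  fit <- fit_adastem(tr, rep(1, 1200), cfg, seed = 1)
  # patch each fold's single-window models to produce the listed values
  for (f in 1:10) {
    for (k in seq_along(fit$folds[[f]][[1]]$models)) {
      if (!is.null(fit$folds[[f]][[1]]$models[[k]])) {
        fit$folds[[f]][[1]]$models[[k]]$cls <- 1
        fit$folds[[f]][[1]]$models[[k]]$reg <- vals[f]
      }
    }
  }
  pt <- tr[1]
  p <- predict_adastem(fit, pt, week = 26)
  expect_equal(p$abundance, median(vals))   # 5.5, robust to the wild fold
  expect_equal(p$coverage, 10L)
  expect_false(p$masked)
  # coverage monotonicity: dropping folds never increases coverage; at 6
  # remaining folds the cell is masked (> 7 rule)
  fit6 <- fit
  fit6$folds <- fit$folds[1:6]
  p6 <- predict_adastem(fit6, pt, week = 26)
  expect_lte(p6$coverage, p$coverage)
  expect_true(p6$masked)
  expect_error(predict_adastem(fit, pt, week = 60), "1..52")
})

test_that("quantile filter masks the stated fraction", {
  d <- data.table::data.table(week = 1L, lat = 0, lon = 1:100,
                              occurrence = 1, abundance = as.numeric(1:100),
                              coverage = 10L, masked = FALSE)
  f <- quantile_filter(d, 0.1)
  expect_equal(sum(!f$masked), 90L)
  expect_true(all(f$abundance[!f$masked] >= quantile(1:100, 0.1)))
  # q = 0: nothing added
  expect_equal(sum(!quantile_filter(d, 0)$masked), 100L)
  # constant abundance: no cell strictly below the quantile
  dc <- data.table::copy(d)[, abundance := 7]
  expect_equal(sum(!quantile_filter(dc, 0.1)$masked), 100L)
  # all masked: warning, unchanged
  da <- data.table::copy(d)[, masked := TRUE]
  expect_warning(quantile_filter(da, 0.1), "masked")
})

test_that("ensemble recovers a step-function range (Jaccard >= 0.6)", {
  set.seed(21)
  n <- 6000                     # dense enough for >= 50 checklists per stixel
  tr <- data.table::data.table(
    lon = runif(n, 60, 90), lat = runif(n, 15, 45),
    doy = sample.int(365, n, TRUE))
  # true range: a lon/lat block; counts Poisson inside, zero outside
  inside <- tr$lon >= 65 & tr$lon <= 85 & tr$lat >= 20 & tr$lat <= 40
  y <- ifelse(inside, rpois(n, 3) + 1, 0)
  tr[, `:=`(x_lon = lon + rnorm(n, 0, 0.1), x_lat = lat + rnorm(n, 0, 0.1))]

  fit <- fit_adastem(tr, y, adastem_config(), seed = 22,
                     features = c("x_lon", "x_lat"))
  grid <- data.table::CJ(lat = seq(15.5, 44.5, by = 1), lon = seq(60.5, 89.5, by = 1))
  grid[, `:=`(x_lon = lon, x_lat = lat)]
  pred <- quantile_filter(predict_adastem(fit, grid, week = 26), 0.1)
  est <- !pred$masked & pred$abundance > max(pred$abundance[!pred$masked],
                                             na.rm = TRUE) / 2
  truth <- grid$lon >= 65 & grid$lon <= 85 & grid$lat >= 20 & grid$lat <= 40
  jac <- sum(est & truth) / sum(est | truth)
  expect_gte(jac, 0.6)
})
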