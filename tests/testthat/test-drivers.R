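# direction_drivers: annotation, Bayesian regressions, random forest,
# counterfactual prediction.

# Synthetic recovery table: standardised drivers, known coefficients.
driver_table <- function(n = 400, beta = c(wind_cost = 0, vegetation = 0,
                                           temperature = 0.5,
                                           precipitation = 0, elevation = 0),
                         sigma = 0.3, n_species = 10, seed = 21) {
  set.seed(seed)
  X <- matrix(rnorm(n * 5), n, 5,
              dimnames = list(NULL, names(beta)))
  X <- scale(X)
  tab <- data.table::as.data.table(X)
  tab[, azimuth := as.vector(X %*% beta) + rnorm(n, 0, sigma)]
  tab[, species := sample(sprintf("S%02d", seq_len(n_species)), n, TRUE)]
  tab[, season := sample(c("spring", "autumn"), n, TRUE)]
  tab[, stage := sample(c("west", "central", "east"), n, TRUE)]
  tab
}

test_that("segment annotation takes endpoint means and standardises", {
  w <- test_world()
  seg <- data.table::data.table(
    species = "SPX",
    from_lat = c(30, 40), from_lon = c(80, 90),
    to_lat = c(20, 35), to_lon = c(85, 100),
    azimuth = c(150, 110), distance_km = c(1000, 900),
    season = "autumn", stage = "central",
    direction_class = c("latitudinal", "longitudinal"))
  wc <- wind_cost_layer(w$env_m, months = 9, n_pairs = 60, seed = 5)
  ann <- annotate_segments(seg, w$env_m, wc)
  expect_true(all(c("wind_cost", "vegetation", "temperature",
                    "precipitation", "elevation") %in% names(ann)))
  # endpoint mean for a known layer
  layers <- windward:::env_annual_layers(w$env_m)
  ij1 <- windward:::env_cell(w$env_m, 30, 80)
  ij2 <- windward:::env_cell(w$env_m, 20, 85)
  expect_equal(ann$temperature[1],
               (layers$temperature[ij1] + layers$temperature[ij2]) / 2)
  # out-of-coverage segments dropped with a message
  far <- data.table::copy(seg)[1, `:=`(from_lat = -50, from_lon = -100)]
  expect_message(a2 <- annotate_segments(far, w$env_m, wc), "dropped")
  expect_equal(nrow(a2), 1L)

  # standardisation contract
  tab <- driver_table()
  std <- windward:::standardize_drivers(data.table::copy(tab))
  for (cn in windward:::DRIVER_COLS) {
    expect_lt(abs(mean(std[[cn]])), 1e-8)
    expect_lt(abs(sd(std[[cn]]) - 1), 1e-8)
  }
  const <- data.table::copy(tab)[, wind_cost := 7]
  expect_error(windward:::standardize_drivers(const), "zero-variance")
})

test_that("season x stage enumeration yields exactly 8 models", {
  grid <- enumerate_driver_models()
  expect_equal(nrow(grid), 8L)
  expect_setequal(grid$season, c("spring", "autumn"))
  expect_setequal(grid$stage, c("overall", "east", "central", "west"))
  expect_equal(nrow(unique(grid)), 8L)
})

test_that("Bayesian regression recovers known coefficients", {
  tab <- driver_table()
  fit <- fit_bayes(tab, hierarchical = TRUE, seed = 22,
                   chains = 4, tune = 1000, draws = 1000)
  s <- fit$summary
  bt <- s[parameter == "beta_temperature"]
  expect_gt(bt$q3, 0); expect_lt(bt$q3, 0.5); expect_gt(bt$q97, 0.5)
  for (p in paste0("beta_", c("wind_cost", "vegetation", "precipitation",
                              "elevation"))) {
    expect_lt(s[parameter == p]$q3, 0)
    expect_gt(s[parameter == p]$q97, 0)
  }
  expect_true(fit$converged)
  # reproducibility of the full fit
  fit2 <- fit_bayes(tab, hierarchical = TRUE, seed = 22,
                    chains = 4, tune = 1000, draws = 1000)
  expect_identical(fit$summary, fit2$summary)

  # pure-noise response: every interval covers 0
  noise <- driver_table(beta = c(wind_cost = 0, vegetation = 0,
                                 temperature = 0, precipitation = 0,
                                 elevation = 0), seed = 23)
  fn <- fit_bayes(noise, seed = 24, chains = 4, tune = 1000, draws = 1000)
  sb <- fn$summary[grepl("^beta_", parameter)]
  expect_true(all(sb$q3 < 0 & sb$q97 > 0))
  expect_error(fit_bayes(tab[1:5]), "fewer than 10")
})

test_that("94% interval covers the true coefficient in >= 16 of 20 replicates", {
  hits <- 0L
  for (r in 1:20) {
    tab <- driver_table(n = 400, seed = 100 + r)
    fit <- fit_bayes(tab, seed = 200 + r, chains = 2, tune = 400, draws = 600)
    bt <- fit$summary[parameter == "beta_temperature"]
    hits <- hits + as.integer(bt$q3 <= 0.5 && 0.5 <= bt$q97)
  }
  expect_gte(hits, 16L)
})

test_that("random forest ranks the informative driver first", {
  tab <- driver_table(n = 500, seed = 31)
  rf <- fit_rf(tab, seed = 32, n_trees = 150)
  expect_identical(names(rf$importance)[1], "temperature")
  rf2 <- fit_rf(tab, seed = 32, n_trees = 150)
  expect_identical(rf$importance, rf2$importance)
  expect_error(fit_rf(tab[1]), "at least 2")

  # duplicated predictor splits the importance (within a 30% band)
  X <- as.matrix(tab[, windward:::DRIVER_COLS, with = FALSE])
  y <- tab$azimuth
  f1 <- ww_forest(X, y, n_trees = 200, mtry = 2, seed = 33)
  i1 <- forest_importance(f1, seed = 34)["temperature"]
  Xd <- cbind(X, temperature2 = X[, "temperature"])
  f2 <- ww_forest(Xd, y, n_trees = 200, mtry = 2, seed = 33)
  i2 <- forest_importance(f2, seed = 34)
  combined <- i2["temperature"] + i2["temperature2"]
  expect_gt(combined, 0.7 * i1)
  expect_lt(abs(i2["temperature"] - i2["temperature2"]),
            0.5 * combined)       # roughly split between the two copies
})

test_that("counterfactual prediction reuses training standardisation", {
  tab <- driver_table(n = 500, seed = 41)
  rf <- fit_rf(tab, seed = 42, n_trees = 150)

  # identical table -> in-sample predictions
  cf_same <- predict_counterfactual_directions(rf, tab)
  X <- as.matrix(tab[, windward:::DRIVER_COLS, with = FALSE])
  Xs <- sweep(sweep(X, 2, rf$center), 2, rf$scale, "/")
  expect_equal(cf_same$azimuth,
               windward:::wrap360(predict(rf$forest, Xs)))
  expect_equal(sum(cf_same$rose$counts), nrow(tab))

  # leakage guard: shifting a column changes predictions through the
  # TRAINING constants, not a refit standardisation (which would undo the
  # shift entirely)
  shifted <- data.table::copy(tab)[, temperature := temperature + 2]
  cf_shift <- predict_counterfactual_directions(rf, shifted)
  expect_false(isTRUE(all.equal(cf_shift$azimuth, cf_same$azimuth)))
  # refit-standardised predictions would be identical; training-constant
  # standardisation moves the column mean by 2 / scale
  Xs2 <- sweep(sweep(as.matrix(shifted[, windward:::DRIVER_COLS,
                                       with = FALSE]), 2, rf$center),
               2, rf$scale, "/")
  expect_equal(mean(Xs2[, "temperature"]) - mean(Xs[, "temperature"]),
               2 / rf$scale[["temperature"]], tolerance = 1e-12)

  # monotone response probe: azimuth increases with temperature in training,
  # so raising the temperature column raises the mean predicted azimuth
  tab2 <- driver_table(n = 500, beta = c(wind_cost = 0, vegetation = 0,
                                         temperature = 30, precipitation = 0,
                                         elevation = 0), sigma = 5, seed = 43)
  tab2[, azimuth := azimuth + 90]
  rf3 <- fit_rf(tab2, seed = 44, n_trees = 150)
  hi <- data.table::copy(tab2)[, temperature := temperature + 1]
  lo <- data.table::copy(tab2)[, temperature := temperature - 1]
  expect_gt(mean(predict_counterfactual_directions(rf3, hi)$azimuth),
            mean(predict_counterfactual_directions(rf3, lo)$azimuth))

  # schema mismatch rejected by column name
  bad <- data.table::copy(tab)[, wind_cost := NULL]
  expect_error(predict_counterfactual_directions(rf, bad), "wind_cost")
})
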