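# Adaptive spatiotemporal ensemble model: cyclic sliding temporal windows,
# per-fold QuadTree stixelization with seeded origin jitter, per-stixel
# hurdle base models (occurrence classifier x positive-abundance regressor),
# coverage-masked median aggregation across folds, and the post-hoc
# low-abundance quantile filter.

#' AdaSTEM configuration
#'
#' Defaults mirror the published settings: 10 ensemble folds, 25 deg maximum
#' and 5 deg minimum stixel side, at least 50 training checklists per fitted
#' stixel, 50-DOY windows stepping by 20 DOY, and cells predicted only when
#' more than `coverage_min` = 7 folds cover them.
#'
#' @param n_folds,max_len,min_len,min_points,window,step,coverage_min
#'   See description.
#' @param base Base-learner pair, e.g. [base_learner_gbt()] (default) or
#'   [base_learner_mean()]; any list with `fit_class`/`predict_class`/
#'   `fit_reg`/`predict_reg` is accepted.
#' @return Named list.
#' @export
adastem_config <- function(n_folds = 10L, max_len = 25, min_len = 5,
                           min_points = 50L, window = 50L, step = 20L,
                           coverage_min = 7L, base = base_learner_gbt()) {
  list(n_folds = n_folds, max_len = max_len, min_len = min_len,
       min_points = min_points, window = window, step = step,
       coverage_min = coverage_min, base = base)
}

#' Trivial stratified-mean base learner
#'
#' The classifier predicts the training detection rate, the regressor the
#' mean positive count; a hurdle pair of these predicts the stixel's mean
#' response, which makes the single-fold ensemble equal a group-by mean
#' (used by the oracle tests).
#' @return Base-learner list.
#' @export
base_learner_mean <- function() {
  list(
    fit_class = function(X, y) mean(y),
    predict_class = function(m, X) rep(m, nrow(X)),
    fit_reg = function(X, y) mean(y),
    predict_reg = function(m, X) rep(m, nrow(X))
  )
}

#' Gradient-boosted-tree base learner
#'
#' Default hurdle base model: squared-loss boosted trees for both the
#' occurrence classifier (on the 0/1 detection indicator, predictions clamped
#' to \[0, 1\]) and the positive-count regressor.
#'
#' @param n_trees,depth,learning_rate,min_node Boosting settings.
#' @return Base-learner list.
#' @export
base_learner_gbt <- function(n_trees = 25L, depth = 3L, learning_rate = 0.15,
                             min_node = 10L) {
  list(
    fit_class = function(X, y) ww_gbt(X, y, n_trees = n_trees, depth = depth,
                                      learning_rate = learning_rate,
                                      min_node = min_node),
    predict_class = function(m, X) clamp(predict(m, X), 0, 1),
    fit_reg = function(X, y) ww_gbt(X, y, n_trees = n_trees, depth = depth,
                                    learning_rate = learning_rate,
                                    min_node = min_node),
    predict_reg = function(m, X) pmax(0, predict(m, X))
  )
}

#' Cyclic sliding temporal windows
#'
#' Windows start at DOY 1, 1 + step, ... and span `window` days, wrapping
#' across the year boundary (DOY domain 1..366).
#'
#' @param window,step Window length and step in days.
#' @return data.table with `start`, `end` (cyclic) and `center`.
#' @export
temporal_windows <- function(window = 50L, step = 20L) {
  if (step <= 0 || window < step || window > 366) {
    stop("need 0 < step <= window <= 366", call. = FALSE)
  }
  start <- seq(1L, 366L, by = as.integer(step))
  end <- ((start + as.integer(window) - 1L - 1L) %% 366L) + 1L
  center <- ((start + (window - 1) / 2 - 1) %% 366) + 1
  data.table::data.table(start = start, end = end, center = center)
}

# Is DOY inside the cyclic window [start, end]? Vectorised over both the
# DOYs and the windows (recycling).
doy_in_window <- function(doy, start, end) {
  wrap <- start > end
  (!wrap & doy >= start & doy <= end) | (wrap & (doy >= start | doy <= end))
}

# Cyclic DOY distance on a 366-day year.
doy_dist <- function(a, b) {
  d <- abs(a - b) %% 366
  pmin(d, 366 - d)
}

#' QuadTree partition of points
#'
#' A node splits into four equal quadrants iff its side exceeds `max_len`, or
#' halving it stays >= `min_len` and the node holds at least `min_points`
#' points. The root square covers the points and is jittered per fold by a
#' seeded uniform offset in \[0, min_len) per axis, decorrelating folds.
#'
#' @param lon,lat Point coordinates (degrees).
#' @param fold_seed Integer seed for the origin jitter.
#' @param max_len,min_len,min_points Split thresholds.
#' @param root Optional `c(lon0, lat0, side)` overriding the automatic root.
#' @return data.table of leaves: `lon0`, `lon1`, `lat0`, `lat1`, `n`.
#' @export
quadtree_partition <- function(lon, lat, fold_seed = 1L, max_len = 25,
                               min_len = 5, min_points = 50L, root = NULL) {
  if (length(lon) == 0L) {
    return(data.table::data.table(lon0 = numeric(), lon1 = numeric(),
                                  lat0 = numeric(), lat1 = numeric(),
                                  n = integer()))
  }
  if (is.null(root)) {
    jit <- with_seed(fold_seed, runif(2, 0, min_len))
    side <- max(diff(range(lon)), diff(range(lat))) + min_len
    root <- c(min(lon) - jit[1], min(lat) - jit[2], side)
  }
  leaves <- list()
  recurse <- function(x0, y0, side, idx) {
    n <- length(idx)
    split <- (side > max_len) ||
      (side / 2 >= min_len && n >= min_points)
    if (!split) {
      leaves[[length(leaves) + 1L]] <<- data.table::data.table(
        lon0 = x0, lon1 = x0 + side, lat0 = y0, lat1 = y0 + side, n = n)
      return(invisible())
    }
    h <- side / 2
    xm <- x0 + h; ym <- y0 + h
    lx <- lon[idx] < xm; ly <- lat[idx] < ym
    recurse(x0, y0, h, idx[lx & ly])
    recurse(xm, y0, h, idx[!lx & ly])
    recurse(x0, ym, h, idx[lx & !ly])
    recurse(xm, ym, h, idx[!lx & !ly])
  }
  recurse(root[1], root[2], root[3], seq_along(lon))
  out <- data.table::rbindlist(leaves)
  out[, leaf_id := .I]
  out[]
}

# Index of the leaf containing each point ([lo, hi) convention; NA outside).
leaf_locate <- function(leaves, lon, lat) {
  out <- rep(NA_integer_, length(lon))
  for (k in seq_len(nrow(leaves))) {
    inl <- lon >= leaves$lon0[k] & lon < leaves$lon1[k] &
      lat >= leaves$lat0[k] & lat < leaves$lat1[k]
    out[inl] <- leaves$leaf_id[k]
  }
  out
}

#' Fit the stixel ensemble
#'
#' For each of `n_folds` folds, each temporal window, and each QuadTree leaf
#' holding at least `min_points` training checklists, fits a hurdle pair: an
#' occurrence classifier on detected/not plus an abundance regressor on the
#' positive counts. A stixel whose detections are all zero keeps a
#' classifier-only model predicting zero abundance.
#'
#' @param train data.frame/data.table with `lon`, `lat`, `doy` and the
#'   feature columns named in `features`.
#' @param responses Per-checklist counts for one species (same order).
#' @param config [adastem_config()].
#' @param seed Integer seed.
#' @param features Character vector of feature column names (default: all
#'   numeric columns except lon/lat/doy).
#' @return Object of class `StixelEnsemble`.
#' @export
fit_adastem <- function(train, responses, config = adastem_config(),
                        seed = 1L, features = NULL) {
  tr <- data.table::as.data.table(train)
  stopifnot(all(c("lon", "lat", "doy") %in% names(tr)),
            nrow(tr) == length(responses))
  if (is.null(features)) {
    num <- names(tr)[vapply(tr, is.numeric, TRUE)]
    features <- setdiff(num, c("lon", "lat", "doy"))
  }
  X_all <- as.matrix(tr[, features, with = FALSE])
  y <- as.numeric(responses)
  wins <- temporal_windows(config$window, config$step)
  folds <- vector("list", config$n_folds)

  with_seed(seed, {
    for (f in seq_len(config$n_folds)) {
      fold_seed <- sample.int(.Machine$integer.max %/% 2, 1L)
      windows <- vector("list", nrow(wins))
      for (w in seq_len(nrow(wins))) {
        inw <- which(doy_in_window(tr$doy, wins$start[w], wins$end[w]))
        leaves <- quadtree_partition(tr$lon[inw], tr$lat[inw],
                                     fold_seed = fold_seed,
                                     max_len = config$max_len,
                                     min_len = config$min_len,
                                     min_points = config$min_points)
        models <- vector("list", nrow(leaves))
        if (nrow(leaves) > 0) {
          loc <- leaf_locate(leaves, tr$lon[inw], tr$lat[inw])
          for (k in seq_len(nrow(leaves))) {
            rows <- inw[which(loc == leaves$leaf_id[k])]
            if (length(rows) < config$min_points) next
            Xk <- X_all[rows, , drop = FALSE]
            det <- as.numeric(y[rows] > 0)
            cls <- config$base$fit_class(Xk, det)
            pos <- rows[y[rows] > 0]
            reg <- if (length(pos) > 0) {
              config$base$fit_reg(X_all[pos, , drop = FALSE], y[pos])
            } else NULL   # all-zero stixel: classifier-only, abundance 0
            models[[k]] <- list(cls = cls, reg = reg, n = length(rows))
          }
        }
        windows[[w]] <- list(leaves = leaves, models = models)
      }
      folds[[f]] <- windows
    }
  })
  structure(list(folds = folds, windows = wins, features = features,
                 config = config, seed = as.integer(seed)),
            class = "StixelEnsemble")
}

#' @exportS3Method base::print
print.StixelEnsemble <- function(x, ...) {
  nfit <- sum(vapply(x$folds, function(f) sum(vapply(f, function(w)
    sum(!vapply(w$models, is.null, TRUE)), 0L)), 0L))
  cat(sprintf("<StixelEnsemble> %d folds x %d windows, %d fitted stixels\n",
              length(x$folds), nrow(x$windows), nfit))
  invisible(x)
}

#' Predict a weekly distribution
#'
#' Per fold, a query takes the window whose centre is nearest its DOY (ties
#' to the earlier window) and the leaf containing it; predictions are
#' aggregated across folds by the median, with the ensemble coverage count
#' retained and cells covered by `coverage_min` (7) or fewer folds masked.
#'
#' @param model A `StixelEnsemble`.
#' @param grid data.frame/data.table of prediction points with `lon`, `lat`
#'   and the training feature columns.
#' @param week Week of year (1-52).
#' @return `WeeklyDistribution` data.table: `week`, `lat`, `lon`,
#'   `occurrence`, `abundance`, `coverage`, `masked`.
#' @export
predict_adastem <- function(model, grid, week) {
  if (length(week) != 1L || week < 1 || week > 52) {
    stop("`week` must be in 1..52", call. = FALSE)
  }
  g <- data.table::as.data.table(grid)
  Xg <- as.matrix(g[, model$features, with = FALSE])
  doy <- week_mid_doy(week)
  # prediction points carry the queried week's DOY as their temporal feature
  if ("temporal_doy" %in% colnames(Xg)) Xg[, "temporal_doy"] <- doy
  wins <- model$windows
  d <- doy_dist(wins$center, doy)
  w_sel <- which(d == min(d))[1]                 # ties -> earlier window
  np <- nrow(g)
  preds_occ <- matrix(NA_real_, np, length(model$folds))
  preds_ab <- matrix(NA_real_, np, length(model$folds))
  for (f in seq_along(model$folds)) {
    wobj <- model$folds[[f]][[w_sel]]
    if (nrow(wobj$leaves) == 0L) next
    loc <- leaf_locate(wobj$leaves, g$lon, g$lat)
    for (k in seq_len(nrow(wobj$leaves))) {
      mk <- wobj$models[[k]]
      if (is.null(mk)) next
      rows <- which(loc == wobj$leaves$leaf_id[k])
      if (!length(rows)) next
      Xr <- Xg[rows, , drop = FALSE]
      occ <- model$config$base$predict_class(mk$cls, Xr)
      ab <- if (is.null(mk$reg)) rep(0, length(rows)) else
        model$config$base$predict_reg(mk$reg, Xr)
      preds_occ[rows, f] <- occ
      preds_ab[rows, f] <- occ * ab
    }
  }
  coverage <- rowSums(!is.na(preds_ab))
  med <- function(m) apply(m, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r)) median(r) else NA_real_
  })
  out <- data.table::data.table(
    week = as.integer(week), lat = g$lat, lon = g$lon,
    occurrence = med(preds_occ), abundance = med(preds_ab),
    coverage = as.integer(coverage),
    masked = coverage <= model$config$coverage_min)
  data.table::setattr(out, "class", c("WeeklyDistribution", class(out)))
  out
}

#' Mask cells below an abundance quantile
#'
#' Per species-week, additionally masks unmasked cells whose abundance is
#' strictly below the `q`-quantile of unmasked abundances (the published
#' post-hoc 0.1-quantile reliability filter).
#'
#' @param dist A `WeeklyDistribution` (may hold several weeks/species).
#' @param q Quantile (default 0.1).
#' @return The filtered distribution.
#' @export
quantile_filter <- function(dist, q = 0.1) {
  d <- data.table::copy(data.table::as.data.table(dist))
  by_cols <- intersect(c("species", "week"), names(d))
  if (all(d$masked)) {
    warning("all cells already masked; quantile filter left input unchanged")
    return(d)
  }
  d[, masked := {
    un <- !masked
    if (any(un)) {
      thr <- quantile(abundance[un], q, na.rm = TRUE)
      masked | (!masked & abundance < thr)
    } else masked
  }, by = by_cols]
  d[]
}
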