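# Tree-ensemble learners built on the compiled CART kernel: a bagged random
# forest with out-of-bag permutation importance, and squared-loss gradient
# boosting. These back the stixel base models and the migration-direction
# random forest.

#' @useDynLib windward, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

cart_fit <- function(X, y, mtry = ncol(X), min_node = 5L, max_depth = 20L,
                     rows = seq_len(nrow(X))) {
  .cart_grow(X, y, as.integer(rows - 1L), as.integer(mtry),
             as.integer(min_node), as.integer(max_depth))
}

cart_pred <- function(tree, X) .cart_predict(tree, X)

#' Random forest regression
#'
#' Bagged CART trees with per-node random feature subsampling. Deterministic
#' given `seed`.
#'
#' @param X Numeric matrix (rows = cases).
#' @param y Numeric response.
#' @param n_trees Number of trees (default 200).
#' @param mtry Features tried per split (default `max(1, floor(p / 3))`).
#' @param min_node Minimum node size (default 5).
#' @param max_depth Maximum tree depth (default 25).
#' @param seed Integer seed.
#' @return Object of class `ww_forest`.
#' @export
ww_forest <- function(X, y, n_trees = 200L, mtry = NULL, min_node = 5L,
                      max_depth = 25L, seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 rows", call. = FALSE)
  mtry <- mtry %||% max(1L, floor(ncol(X) / 3))
  with_seed(seed, {
    trees <- vector("list", n_trees)
    oob <- vector("list", n_trees)
    n <- nrow(X)
    for (b in seq_len(n_trees)) {
      rows <- sample.int(n, n, replace = TRUE)
      trees[[b]] <- cart_fit(X, y, mtry = mtry, min_node = min_node,
                             max_depth = max_depth, rows = rows)
      oob[[b]] <- setdiff(seq_len(n), unique(rows))
    }
    structure(list(trees = trees, oob = oob, X = X, y = y, mtry = mtry,
                   colnames = colnames(X), seed = as.integer(seed)),
              class = "ww_forest")
  })
}

#' @export
predict.ww_forest <- function(object, newdata, ...) {
  Xn <- as.matrix(newdata)[, , drop = FALSE]
  preds <- vapply(object$trees, function(tr) cart_pred(tr, Xn),
                  numeric(nrow(Xn)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  rowMeans(preds)
}

#' Out-of-bag permutation importance
#'
#' Mean increase in out-of-bag squared error when one predictor column is
#' permuted, averaged over trees. Deterministic given `seed`.
#'
#' @param forest A [ww_forest()].
#' @param seed Integer seed for the permutations.
#' @return Named numeric vector, decreasing order.
#' @export
forest_importance <- function(forest, seed = 1L) {
  X <- forest$X; y <- forest$y; p <- ncol(X)
  imp <- numeric(p)
  cnt <- numeric(p)
  with_seed(seed, {
    for (b in seq_along(forest$trees)) {
      o <- forest$oob[[b]]
      if (length(o) < 2L) next
      base <- mean((cart_pred(forest$trees[[b]], X[o, , drop = FALSE]) - y[o])^2)
      for (j in seq_len(p)) {
        Xp <- X[o, , drop = FALSE]
        Xp[, j] <- Xp[sample.int(length(o)), j]
        err <- mean((cart_pred(forest$trees[[b]], Xp) - y[o])^2)
        imp[j] <- imp[j] + (err - base)
        cnt[j] <- cnt[j] + 1
      }
    }
  })
  imp <- imp / pmax(1, cnt)
  names(imp) <- forest$colnames %||% paste0("x", seq_len(p))
  sort(imp, decreasing = TRUE)
}

#' Gradient-boosted regression trees (squared loss)
#'
#' @inheritParams ww_forest
#' @param depth Tree depth (default 3).
#' @param learning_rate Shrinkage (default 0.1).
#' @param n_trees Boosting rounds (default 50).
#' @return Object of class `ww_gbt`.
#' @export
ww_gbt <- function(X, y, n_trees = 50L, depth = 3L, learning_rate = 0.1,
                   min_node = 10L, seed = 1L) {
  X <- as.matrix(X)
  with_seed(seed, {
    f0 <- mean(y)
    resid <- y - f0
    trees <- vector("list", n_trees)
    for (b in seq_len(n_trees)) {
      tr <- cart_fit(X, resid, mtry = ncol(X), min_node = min_node,
                     max_depth = depth)
      resid <- resid - learning_rate * cart_pred(tr, X)
      trees[[b]] <- tr
    }
    structure(list(f0 = f0, trees = trees, learning_rate = learning_rate,
                   colnames = colnames(X)), class = "ww_gbt")
  })
}

#' @export
predict.ww_gbt <- function(object, newdata, ...) {
  Xn <- as.matrix(newdata)
  out <- rep(object$f0, nrow(Xn))
  for (tr in object$trees) out <- out + object$learning_rate * cart_pred(tr, Xn)
  out
}
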