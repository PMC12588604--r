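# Maximum-entropy-style presence-background niche model: linear + quadratic
# features per environmental layer, L1-penalised "infinitely weighted"
# logistic likelihood (the lasso path machinery of glmnet, the same backbone
# the field's maxnet uses), logistic suitability output, clamping to the
# training ranges at projection time, and bootstrap AUC evaluation.

# Feature expansion: each layer scaled to [0, 1] by its training range, plus
# its square. Constant layers are dropped (coefficients fixed at 0).
niche_expand <- function(E, ranges) {
  nm <- colnames(E)
  out <- matrix(0, nrow(E), 2 * length(nm))
  cn <- character(2 * length(nm))
  for (k in seq_along(nm)) {
    rng <- ranges[[nm[k]]]
    x <- if (diff(rng) > 0) (E[, k] - rng[1]) / diff(rng) else rep(0, nrow(E))
    out[, 2 * k - 1] <- x
    out[, 2 * k] <- x^2
    cn[c(2 * k - 1, 2 * k)] <- paste0(nm[k], c("", "_sq"))
  }
  colnames(out) <- cn
  out
}

#' Fit the maximum-entropy-style niche model
#'
#' Maximises the L1-penalised presence-vs-background log-likelihood over
#' linear + quadratic features of the environmental layers, with the
#' regularisation-by-sample-size schedule of the classic implementation
#' (multiplier interpolated over the presence count) and a background weight
#' of 100.
#'
#' @param presence_env Matrix/data.frame of environment at presence points
#'   (named columns, one per layer).
#' @param background_env Same columns at background points.
#' @param reg_multiplier Regularisation multiplier (default 1).
#' @param maxit Optimiser iteration cap (default 1e5 coordinate-descent passes; the original tool's "1000 iterations" counts its sequential algorithm's steps, which do not map 1:1).
#' @return Object of class `NicheModel` with coefficients, training ranges
#'   (used for clamping) and the logistic output transform.
#' @export
fit_maxent <- function(presence_env, background_env, reg_multiplier = 1,
                       maxit = 100000L) {
  P <- as.matrix(presence_env); B <- as.matrix(background_env)
  stopifnot(identical(colnames(P), colnames(B)))
  if (nrow(P) < 10L) stop("need >= 10 presence points", call. = FALSE)
  ranges <- lapply(seq_len(ncol(P)), function(k) range(P[, k], B[, k]))
  names(ranges) <- colnames(P)
  constant <- vapply(ranges, function(r) diff(r) <= 0, TRUE)
  if (any(constant) && !all(constant)) {
    warning(sprintf("constant layer(s) %s: coefficients fixed at 0",
                    paste(names(ranges)[constant], collapse = ", ")))
  }
  X <- rbind(niche_expand(P, ranges), niche_expand(B, ranges))
  pvec <- c(rep(1, nrow(P)), rep(0, nrow(B)))
  np <- nrow(P)
  # "infinitely weighted" background: total background weight fixed at
  # 100 x the presence count, so growing the background sample (same
  # empirical distribution) leaves the fit invariant
  w <- ifelse(pvec == 1, 1, 100 * np / nrow(B))
  if (all(constant)) {
    warning("all layers constant: uniform suitability model")
    beta <- c(qlogis(1 / 101), rep(0, ncol(X)))   # presence:background 1:100
    names(beta) <- c("(Intercept)", colnames(X))
    return(structure(list(beta = beta, ranges = ranges, layers = colnames(P),
                          reg_multiplier = reg_multiplier, converged = TRUE),
                     class = "NicheModel"))
  }
  # regularisation-by-sample-size schedule for linear+quadratic feature
  # sets: lambda_j = r(np) * s_j / sqrt(np) with s_j the presence-sample sd
  rm_sched <- approx(x = c(10, 30, 100), y = c(1.0, 0.6, 0.5),
                     xout = clamp(np, 10, 100), rule = 2)$y * reg_multiplier
  sds <- apply(X[pvec == 1, , drop = FALSE], 2, sd)
  pf <- rm_sched * pmax(sds, 0.05) / sqrt(np)
  pf[!is.finite(pf) | pf <= 0] <- 1
  lambdas <- 10^seq(4, 0, length.out = 200) * mean(pf) * sum(pvec) / sum(w)
  converged <- TRUE
  fit <- withCallingHandlers(
    glmnet::glmnet(X, pvec, family = "binomial", weights = w,
                   standardize = FALSE, penalty.factor = pf,
                   lambda = lambdas, maxit = maxit),
    warning = function(w_) {
      if (grepl("Convergence", conditionMessage(w_))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    })
  beta <- as.numeric(coef(fit, s = min(fit$lambda)))
  names(beta) <- c("(Intercept)", colnames(X))
  if (!converged) message("fit_maxent: iteration cap reached before convergence")
  structure(list(beta = beta, ranges = ranges, layers = colnames(P),
                 reg_multiplier = reg_multiplier, converged = converged),
            class = "NicheModel")
}

# Logistic suitability at environment rows, clamping to training ranges.
niche_suitability <- function(model, E) {
  E <- as.matrix(E)
  E <- E[, model$layers, drop = FALSE]
  for (k in seq_along(model$layers)) {
    rng <- model$ranges[[model$layers[k]]]
    E[, k] <- clamp(E[, k], rng[1], rng[2])
  }
  X <- niche_expand(E, model$ranges)
  as.vector(plogis(model$beta[1] + X %*% model$beta[-1]))
}

#' @export
predict.NicheModel <- function(object, newdata, ...) {
  niche_suitability(object, newdata)
}

# Rank-based (Mann-Whitney) AUC of positive scores vs negative scores.
auc_rank <- function(score_pos, score_neg) {
  r <- rank(c(score_pos, score_neg))
  n1 <- length(score_pos); n0 <- length(score_neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap AUC evaluation
#'
#' The published protocol: `n_boot` replicates, each holding out a random
#' 25% of presence locations, refitting on the remaining 75%, and scoring
#' the held-out presences against the background with the rank-based AUC.
#' Deterministic given `seed`. Replicates with fewer than 2 held-out
#' presences are skipped with a log entry.
#'
#' @param presence_env,background_env As in [fit_maxent()].
#' @param n_boot Replicates (default 20).
#' @param train_frac Training fraction (default 0.75).
#' @param seed Integer seed.
#' @param ... Passed to [fit_maxent()].
#' @return `AUCSummary` list: per-replicate `auc`, `mean`, `sd`.
#' @export
evaluate_auc <- function(presence_env, background_env, n_boot = 20L,
                         train_frac = 0.75, seed = 1L, ...) {
  P <- as.matrix(presence_env)
  n <- nrow(P)
  if (floor(n * train_frac) < 10L) stop("too few presences to split", call. = FALSE)
  aucs <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      tr <- sample.int(n, floor(n * train_frac))
      ho <- setdiff(seq_len(n), tr)
      if (length(ho) < 2L) {
        message(sprintf("replicate %d skipped: < 2 held-out presences", b))
        return(NA_real_)
      }
      m <- fit_maxent(P[tr, , drop = FALSE], background_env, ...)
      auc_rank(niche_suitability(m, P[ho, , drop = FALSE]),
               niche_suitability(m, background_env))
    }, 0)
  })
  aucs <- aucs[!is.na(aucs)]
  structure(list(auc = aucs, mean = mean(aucs), sd = sd(aucs),
                 n_boot = n_boot, train_frac = train_frac),
            class = "AUCSummary")
}

#' @exportS3Method base::print
print.AUCSummary <- function(x, ...) {
  cat(sprintf("<AUCSummary> %d replicates: mean %.3f (sd %.3f)\n",
              length(x$auc), x$mean, x$sd))
  invisible(x)
}

#' Project a niche model onto an environment stack
#'
#' Features are clamped to the training ranges before the coefficients are
#' applied (the niche-conservatism assumption enters only as "same
#' coefficients, different environment"). Projecting onto the training
#' environment reproduces the in-sample suitability exactly.
#'
#' @param model A `NicheModel`.
#' @param env An `EnvironmentStack` providing every training layer (annual
#'   summaries: `temperature`, `precipitation`, `elevation`, `vegetation`).
#' @return data.table `lat`, `lon`, `suitability`.
#' @export
project_niche <- function(model, env) {
  layers <- env_annual_layers(env)
  missing <- setdiff(model$layers, names(layers))
  if (length(missing)) {
    stop(sprintf("environment stack lacks layer(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  nlat <- length(env$lat); nlon <- length(env$lon)
  E <- vapply(model$layers, function(nm) as.vector(layers[[nm]]),
              numeric(nlat * nlon))
  lat_m <- matrix(env$lat, nlat, nlon)
  lon_m <- matrix(env$lon, nlat, nlon, byrow = TRUE)
  data.table::data.table(lat = as.vector(lat_m), lon = as.vector(lon_m),
                         suitability = niche_suitability(model, E))
}
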