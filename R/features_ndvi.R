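# NDVI phenology features (6 columns): a penalised cubic B-spline smoother
# (30 basis functions, second-difference penalty, GCV-chosen smoothing
# parameter) interpolates the sparse vegetation-index observations to daily
# resolution; the features are the median/max/min of the smoothed curve and
# of its first derivative against day of year ("green wave").

NDVI_COLS <- c("ndvi_median", "ndvi_max", "ndvi_min",
               "dndvi_median", "dndvi_max", "dndvi_min")

# Cubic B-spline basis with `nbasis` functions over [lo, hi]: equally spaced
# knots extended 3 steps beyond each boundary (the standard P-spline layout,
# whose coefficient second-difference penalty leaves linear functions
# unpenalised).
pspline_basis <- function(x, nbasis = 30L, lo = 1, hi = 366) {
  h <- (hi - lo) / (nbasis - 3L)
  knots <- seq(lo - 3 * h, hi + 3 * h, by = h)
  splines::splineDesign(knots, x, ord = 4L, outer.ok = FALSE)
}

# Fit the P-spline by GCV over a log-spaced lambda grid; returns the smoothed
# daily curve over 1..365.
pspline_smooth <- function(doy, y, nbasis = 30L) {
  B <- pspline_basis(doy, nbasis)
  D <- diff(diag(nbasis), differences = 2)
  P <- crossprod(D)
  BtB <- crossprod(B); Bty <- crossprod(B, y)
  n <- length(y)
  best <- NULL; best_gcv <- Inf
  for (lam in 10^seq(-4, 7, length.out = 45)) {
    # M is positive definite for lam > 0 (only the zero function lies in
    # both null(B'B) and the second-difference penalty's null space)
    M <- BtB + lam * P
    R <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(R)) next
    beta <- backsolve(R, backsolve(R, Bty, transpose = TRUE))
    fit <- B %*% beta
    # effective dof = tr(B (B'B + lam P)^-1 B')
    Minv_Bt <- backsolve(R, backsolve(R, t(B), transpose = TRUE))
    edf <- sum(B * t(Minv_Bt))
    rss <- sum((y - fit)^2)
    gcv <- n * rss / max(1e-8, (n - edf))^2
    if (gcv < best_gcv) { best_gcv <- gcv; best <- beta }
  }
  if (is.null(best)) stop("P-spline fit failed", call. = FALSE)
  as.vector(pspline_basis(1:365, nbasis) %*% best)
}

#' NDVI phenology features
#'
#' @param ndvi_series data.frame with columns `doy` and `ndvi`; at least 8
#'   observations across the year (emulating a 16-day cadence).
#' @param nbasis Number of B-spline basis functions (default 30).
#' @return Named numeric vector of length 6: median/max/min of the smoothed
#'   daily NDVI and of its first derivative (per day, central differences).
#' @export
ndvi_features <- function(ndvi_series, nbasis = 30L) {
  s <- as.data.frame(ndvi_series)
  stopifnot(all(c("doy", "ndvi") %in% names(s)))
  s <- s[is.finite(s$doy) & is.finite(s$ndvi), ]
  if (nrow(s) < 8L) {
    stop("need >= 8 NDVI observations across the year", call. = FALSE)
  }
  f <- pspline_smooth(s$doy, s$ndvi, nbasis)
  d <- c(f[2] - f[1], (f[3:365] - f[1:363]) / 2, f[365] - f[364])
  out <- c(median(f), max(f), min(f), median(d), max(d), min(d))
  names(out) <- NDVI_COLS
  out
}
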