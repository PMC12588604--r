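# Convergence diagnostics: rank-normalised split potential-scale-reduction
# (Rhat) and bulk effective sample size, per the modern standard definitions
# (split chains, rank-normalisation via the inverse-normal transform of
# fractional ranks, Geyer initial-monotone-positive-sequence truncation for
# the autocorrelation sum). Cross-checked against coda in the test suite.

# draws: iterations x chains matrix -> split into 2*chains half-chains
split_chains <- function(draws) {
  n <- nrow(draws)
  half <- floor(n / 2)
  cbind(draws[seq_len(half), , drop = FALSE],
        draws[(n - half + 1):n, , drop = FALSE])
}

rank_normalize <- function(draws) {
  s <- length(draws)
  z <- qnorm((rank(as.vector(draws)) - 3 / 8) / (s + 1 / 4))
  matrix(z, nrow(draws), ncol(draws))
}

rhat_basic <- function(draws) {
  m <- ncol(draws); n <- nrow(draws)
  if (n < 4L || m < 2L) return(NA_real_)
  means <- colMeans(draws)
  vars <- apply(draws, 2, var)
  W <- mean(vars)
  B <- n * var(means)
  if (W <= 1e-300) return(1)
  sqrt((W * (n - 1) / n + B / n) / W)
}

#' Rank-normalised split Rhat
#'
#' Maximum of the bulk (rank-normalised) and tail (folded rank-normalised)
#' split potential-scale-reduction factors.
#'
#' @param draws Iterations x chains matrix for one parameter.
#' @return Scalar Rhat.
#' @export
rhat <- function(draws) {
  sp <- split_chains(as.matrix(draws))
  bulk <- rhat_basic(rank_normalize(sp))
  folded <- rhat_basic(rank_normalize(abs(sp - median(sp))))
  max(bulk, folded)
}

# Per-chain autocovariance via FFT (biased, as standard).
autocov_fft <- function(x) {
  n <- length(x)
  xc <- x - mean(x)
  npad <- 2^ceiling(log2(2 * n))
  f <- fft(c(xc, rep(0, npad - n)))
  ac <- Re(fft(f * Conj(f), inverse = TRUE))[1:n] / npad
  ac / n
}

ess_basic <- function(draws) {
  m <- ncol(draws); n <- nrow(draws)
  if (n < 4L || m < 1L) return(NA_real_)
  if (all(abs(draws - draws[1]) < 1e-300)) return(NA_real_)
  acov <- vapply(seq_len(m), function(j) autocov_fft(draws[, j]), numeric(n))
  mean_acov <- rowMeans(acov)
  W <- mean(apply(draws, 2, var))
  var_plus <- W * (n - 1) / n + (if (m > 1) var(colMeans(draws)) else 0)
  if (var_plus <= 1e-300) return(NA_real_)
  rho <- 1 - (W - mean_acov) / var_plus       # rho[1] is lag 0
  # Geyer: sum consecutive lag pairs (rho_{2k}, rho_{2k+1}) while the pair
  # sum stays positive, then enforce monotone decrease
  P <- numeric(0)
  k <- 0L
  repeat {
    i1 <- 2L * k + 1L; i2 <- 2L * k + 2L
    if (i2 > n) break
    p <- rho[i1] + rho[i2]
    if (!is.finite(p) || p <= 0) break
    P <- c(P, p)
    k <- k + 1L
  }
  if (length(P) > 1) P <- cummin(P)
  tau <- max(-1 + 2 * sum(P), 1 / log10(n * m))
  min(m * n / tau, m * n * log10(m * n))
}

#' Bulk effective sample size
#'
#' Rank-normalised split-chain effective sample size.
#'
#' @param draws Iterations x chains matrix for one parameter.
#' @return Scalar ESS.
#' @export
ess_bulk <- function(draws) {
  sp <- split_chains(as.matrix(draws))
  ess_basic(rank_normalize(sp))
}
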