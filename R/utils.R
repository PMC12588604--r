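#' @keywords internal
"_PACKAGE"

#' @import stats
#' @importFrom utils head tail modifyList
#' @import data.table
NULL

# Run `expr` under a local RNG state seeded with `seed`, restoring the caller's
# RNG afterwards so generators are pure functions of (parameters, seed).
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Wrap angle in degrees to [0, 360)
wrap360 <- function(x) ((x %% 360) + 360) %% 360

# Signed smallest angular difference a - b in degrees, in (-180, 180]
angle_diff <- function(a, b) {
  d <- wrap360(a - b)
  ifelse(d > 180, d - 360, d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_in <- function(x, choices, name) {
  if (length(x) != 1L || !x %in% choices) {
    stop(sprintf("`%s` must be one of: %s (got '%s')", name,
                 paste(choices, collapse = ", "), paste(x, collapse = ",")),
         call. = FALSE)
  }
  invisible(x)
}
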