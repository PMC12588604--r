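# The 19 standard bioclimatic summaries from daily temperature and
# precipitation series. Daily values are aggregated to months (mean
# temperature; within-month max/min daily temperature as the monthly
# extremes; summed precipitation); quarters are all 12 consecutive 3-month
# windows with December-January wraparound.

BIOCLIM_COLS <- sprintf("bio%02d", 1:19)

#' 19 bioclimatic variables from daily series
#'
#' Definitions (monthly values as above; sd is the n-1 sample sd):
#' BIO1 mean of monthly mean temperature; BIO2 mean monthly diurnal-style
#' range (monthly max - min); BIO3 isothermality 100*BIO2/BIO7; BIO4
#' temperature seasonality 100*sd(monthly means); BIO5/BIO6 max/min monthly
#' extreme temperature; BIO7 BIO5-BIO6; BIO8/BIO9 mean temperature of the
#' wettest/driest quarter; BIO10/BIO11 of the warmest/coldest quarter;
#' BIO12 annual precipitation; BIO13/BIO14 wettest/driest month; BIO15
#' precipitation seasonality 100*sd/mean of monthly precipitation (0 when the
#' mean is 0); BIO16-BIO19 precipitation of the wettest/driest/warmest/
#' coldest quarter.
#'
#' @param daily_temp,daily_precip Numeric vectors of >= 365 daily values
#'   (first 365 used; temperature degC, precipitation mm/day).
#' @return Named numeric vector `bio01`..`bio19`.
#' @export
bioclim_features <- function(daily_temp, daily_precip) {
  if (length(daily_temp) < 365 || length(daily_precip) < 365 ||
      anyNA(daily_temp[1:365]) || anyNA(daily_precip[1:365])) {
    stop("need >= 365 complete daily values of each series", call. = FALSE)
  }
  tt <- daily_temp[1:365]; pp <- daily_precip[1:365]
  mo <- rep(1:12, MONTH_DAYS)
  t_mean <- tapply(tt, mo, mean)
  t_max <- tapply(tt, mo, max)
  t_min <- tapply(tt, mo, min)
  p_m <- tapply(pp, mo, sum)

  qi <- function(q) ((q - 1L):(q + 1L) - 1L) %% 12L + 1L   # wrap quarter
  t_q <- vapply(1:12, function(q) mean(t_mean[qi(q)]), 0)
  p_q <- vapply(1:12, function(q) sum(p_m[qi(q)]), 0)

  bio7 <- max(t_max) - min(t_min)
  bio2 <- mean(t_max - t_min)
  out <- c(
    mean(t_mean),                               # bio01
    bio2,                                       # bio02
    if (bio7 > 0) 100 * bio2 / bio7 else 0,     # bio03
    100 * sd(t_mean),                           # bio04
    max(t_max),                                 # bio05
    min(t_min),                                 # bio06
    bio7,                                       # bio07
    t_q[which.max(p_q)],                        # bio08
    t_q[which.min(p_q)],                        # bio09
    max(t_q),                                   # bio10
    min(t_q),                                   # bio11
    sum(p_m),                                   # bio12
    max(p_m),                                   # bio13
    min(p_m),                                   # bio14
    if (mean(p_m) > 0) 100 * sd(p_m) / mean(p_m) else 0,  # bio15
    max(p_q),                                   # bio16
    min(p_q),                                   # bio17
    p_q[which.max(t_q)],                        # bio18
    p_q[which.min(t_q)]                         # bio19
  )
  names(out) <- BIOCLIM_COLS
  out
}
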