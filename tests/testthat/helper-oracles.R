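# Independent oracles used by the acceptance-style tests.

# Analytic expectation of the annual net urban-minus-rural differential for a
# binary-UHI city with piecewise-linear log-RR curves: the weather anomaly is
# integrated out against its stationary Gaussian density day by day
# (cell-by-cell structure collapses because all urban cells share one offset).
analytic_annual_net <- function(city, rec, offset) {
  doy <- as.integer(format(city$dates, "%j"))
  tbg <- rec$annual_mean_c -
    rec$seasonal_amplitude_c * cos(2 * pi * (doy - 15) / 365.25)
  sig <- rec$weather_sd_c
  e <- seq(-8 * sig, 8 * sig, length.out = 1601)
  w <- stats::dnorm(e, 0, sig)
  w <- w / sum(w)
  shares <- stats::setNames(city$demography$share, city$demography$age_group)
  rates <- stats::setNames(city$baseline$annual_deaths_per_100k,
                           city$baseline$age_group)
  total <- 0
  for (a in AGE_GROUPS) {
    cv <- city$erfs[[a]]$central
    t_lo <- cv$observed_range[1]
    t_hi <- cv$observed_range[2]
    mmt <- cv$mmt
    p <- rec$erf_params[rec$erf_params$age_group == a, ]
    slope_c <- p$log_rr_cold / (mmt - t_lo)
    slope_w <- p$log_rr_warm / (t_hi - mmt)
    af <- function(tt) {
      tt <- pmin(pmax(tt, t_lo), t_hi)
      lrr <- ifelse(tt < mmt, slope_c * (mmt - tt), slope_w * (tt - mmt))
      rr <- exp(lrr)
      (rr - 1) / rr
    }
    tmat <- outer(tbg, e, "+")
    e_rural <- as.vector(af(tmat) %*% w)
    e_urban <- as.vector(af(tmat + offset) %*% w)
    total <- total + shares[[a]] * rates[[a]] * sum(e_urban - e_rural) / 365
  }
  total
}

# relabel urban as rural and vice versa (exclusions untouched)
swap_strata <- function(mask) {
  mask$status <- c(urban_included = "rural_included",
                   rural_included = "urban_included",
                   excluded_water = "excluded_water",
                   excluded_elevation = "excluded_elevation")[mask$status]
  mask
}
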