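# Attribution of daily mortality to non-optimal temperature: AF = (RR - 1)/RR
# per cell x day x age group, warm/cold classification against the age-group
# MMT, extreme-day selection on the domain population-weighted series, and
# aggregation across age groups.

#' Attributable fraction from relative risk
#'
#' `AF = (RR - 1) / RR`. Curves are recentred so RR >= 1 on the U-shape;
#' interpolation can leave RR marginally below 1, which is clamped to 1
#' (AF = 0) down to `1 - 1e-6`; smaller values violate the contract and raise.
#'
#' @param rr Relative risk(s), `>= 1` up to the numerical clamp.
#' @return Attributable fraction(s) in `[0, 1)`.
#' @export
attributable_fraction <- function(rr) {
  if (any(!is.finite(rr)) || any(rr <= 0)) {
    stop("relative risk must be positive and finite")
  }
  if (any(rr < 1 - 1e-6)) {
    stop("relative risk below 1 passed to attributable_fraction; ",
         "curves must be recentred so RR >= 1")
  }
  pmax((rr - 1) / rr, 0)
}

#' Daily attributable number from AF and baseline mortality
#'
#' `AN = AF x (annual deaths per 100k) / days_in_year`, i.e. the annual
#' all-cause baseline spread uniformly over the actual calendar-year length
#' (366 in leap years).
#'
#' @param af Attributable fraction(s).
#' @param baseline Annual deaths per 100,000 for the age group.
#' @param days_in_year 365 or 366.
#' @return Attributable deaths per 100,000 per day.
#' @export
daily_attributable_number <- function(af, baseline, days_in_year) {
  if (any(baseline < 0)) stop("baseline mortality must be non-negative")
  if (!all(days_in_year %in% c(365L, 366L))) {
    stop("days_in_year must be 365 or 366")
  }
  af * baseline / days_in_year
}

#' Classify a temperature as warm or cold for an age group
#'
#' Warm iff strictly above the age group's MMT; a day exactly at the MMT is
#' labelled cold (inert, since AF there is 0). The age dependence of the MMT
#' means the same temperature can be warm for one age group and cold for
#' another.
#'
#' @param t Temperature(s), degrees C.
#' @param mmt The age group's minimum mortality temperature.
#' @return Character vector `"warm"`/`"cold"`.
#' @export
classify_thermal <- function(t, mmt) {
  if (any(!is.finite(t)) || any(!is.finite(mmt))) stop("non-finite inputs")
  ifelse(t > mmt, "warm", "cold")
}

days_in_year_of <- function(dates) {
  yr <- as.integer(format(dates, "%Y"))
  ifelse((yr %% 4 == 0 & yr %% 100 != 0) | yr %% 400 == 0, 366L, 365L)
}

#' Select heat and cold extreme days
#'
#' The warmest and coldest `fraction` (default 2%, i.e. 22 of a 1096-day
#' three-year window) of days, ranked by the domain population-weighted daily
#' mean temperature over included cells. `k` is round-half-up of
#' `fraction x n_days`; ties at the cutoff are broken toward the earlier date.
#'
#' @param cube A [temperature_cube()].
#' @param population population_count [static_layer()].
#' @param mask An [build_analysis_mask()] result.
#' @param fraction Tail fraction in `(0, 0.5]`.
#' @return List with `heat_days`, `cold_days` (Date vectors of equal length
#'   `k`) and `domain_series` (data frame `date`, `tmean_c`).
#' @export
find_extreme_days <- function(cube, population, mask, fraction = 0.02) {
  stopifnot(inherits(cube, "temperature_cube"))
  if (fraction <= 0 || fraction > 0.5) {
    stop("fraction must lie in (0, 0.5]")
  }
  n <- length(cube$dates)
  if (n < 1 / fraction) stop("too few days for the requested tail fraction")
  idx <- mask_cells(mask, "all")
  w <- (if (inherits(population, "static_layer")) population$values
        else as.numeric(population))[idx]
  if (sum(w) <= 0) stop("domain population weight is non-positive")
  series <- as.vector(cube$values[, idx, drop = FALSE] %*% w) / sum(w)
  k <- floor(fraction * n + 0.5)
  # stable order: ties at the cutoff resolve to the earlier date
  heat <- order(-series)[seq_len(k)]
  cold <- order(series)[seq_len(k)]
  list(heat_days = cube$dates[sort(heat)], cold_days = cube$dates[sort(cold)],
       k = k, domain_series = data.frame(date = cube$dates, tmean_c = series))
}

#' Aggregate per-age attributable numbers across age groups
#'
#' Weighted sum with the adult age-structure shares (per-100k rates weighted
#' by population shares give the all-adult per-100k rate).
#'
#' @param per_age_an Named numeric, AN per 100k per age group.
#' @param shares Named age-structure shares summing to 1.
#' @return Scalar all-adult AN per 100k.
#' @export
aggregate_ages <- function(per_age_an, shares) {
  if (abs(sum(shares) - 1) > 1e-9) stop("shares must sum to 1")
  if (!setequal(names(per_age_an), names(shares))) {
    stop("age groups of values and shares do not match")
  }
  sum(shares[names(per_age_an)] * per_age_an)
}

#' Per-cell, per-day attribution for a city (central curves)
#'
#' The exact (per-cell x day) attribution engine: evaluates each age group's
#' central ERF at every included cell and day, converts RR to AF (Eq. AF =
#' (RR-1)/RR) and to daily attributable numbers, classifies each cell-day as
#' warm or cold against the age-specific MMT, and reduces to unweighted daily
#' spatial means per stratum (the individual-inhabitant perspective). Per-cell
#' day-set aggregates needed by the imperviousness and exposure-bias analyses
#' are accumulated alongside.
#'
#' @param cube A [temperature_cube()].
#' @param mask An [build_analysis_mask()] result.
#' @param erfs Named list (per age group) of central [erf_curve()]s or
#'   [erf_ensemble()]s (central curve used).
#' @param baseline Named annual deaths per 100k per age group.
#' @param age_structure Named adult shares per age group (sum 1).
#' @param extremes Optional [find_extreme_days()] result; enables per-cell
#'   extreme-day aggregates.
#' @param classification `"cell"` (each cell's own temperature against the
#'   MMT, the default) or `"domain"` (whole-domain day label from the
#'   population-weighted mean series in `extremes`).
#' @return A `daily_attribution` object: `series` (data frame with one row
#'   per date x age group incl. `"all"`: urban/rural mean AN, total and
#'   heat/cold components), `cell_stats` (per-cell data frame of annual and
#'   extreme-day aggregates, all-age), `mmt` (named per age).
#' @export
attribute_city <- function(cube, mask, erfs, baseline, age_structure,
                           extremes = NULL,
                           classification = c("cell", "domain")) {
  classification <- match.arg(classification)
  stopifnot(inherits(cube, "temperature_cube"),
            inherits(mask, "analysis_mask"))
  ages <- names(erfs)
  if (!setequal(ages, AGE_GROUPS)) {
    stop("erfs must be a named list covering the five adult age groups")
  }
  if (classification == "domain" && is.null(extremes)) {
    stop("domain-level classification needs the extremes domain series")
  }
  u <- mask_cells(mask, "urban")
  r <- mask_cells(mask, "rural")
  if (length(u) == 0L) stop("no included urban cells")
  if (length(r) == 0L) stop("no included rural cells")
  inc <- c(u, r)
  iu <- seq_along(u)
  ir <- length(u) + seq_along(r)
  dates <- cube$dates
  nd <- length(dates)
  diy <- days_in_year_of(dates)
  yrs <- as.integer(format(dates, "%Y"))
  n_years <- length(unique(yrs))
  Tm <- cube$values[, inc, drop = FALSE]

  heat_idx <- cold_idx <- integer(0)
  if (!is.null(extremes)) {
    heat_idx <- match(extremes$heat_days, dates)
    cold_idx <- match(extremes$cold_days, dates)
  }

  series <- list()
  mmts <- stats::setNames(numeric(length(AGE_GROUPS)), AGE_GROUPS)
  # all-age accumulators; the cold component is total minus heat at every
  # level, so heat + cold = total holds exactly, not just to rounding
  tot_all <- heat_all <- matrix(0, nd, length(inc))
  mk_rows <- function(an, an_heat, a) {
    ut <- rowMeans(an[, iu, drop = FALSE])
    uh <- rowMeans(an_heat[, iu, drop = FALSE])
    rt <- rowMeans(an[, ir, drop = FALSE])
    rh <- rowMeans(an_heat[, ir, drop = FALSE])
    data.frame(date = dates, age_group = a,
               urban_total = ut, urban_heat = uh, urban_cold = ut - uh,
               rural_total = rt, rural_heat = rh, rural_cold = rt - rh)
  }
  for (a in AGE_GROUPS) {
    curve <- erfs[[a]]
    if (inherits(curve, "erf_ensemble")) curve <- curve$central
    stopifnot(inherits(curve, "erf_curve"))
    mmts[[a]] <- curve$mmt
    lrr <- curve$interp(pmin(pmax(Tm, curve$observed_range[1]),
                             curve$observed_range[2]))
    an <- attributable_fraction(exp(lrr)) * baseline[[a]] / diy  # recycles by row
    if (classification == "cell") {
      warm <- Tm > curve$mmt
    } else {
      warm <- matrix(extremes$domain_series$tmean_c > curve$mmt,
                     nd, length(inc))
    }
    an_heat <- an * warm
    sh <- age_structure[[a]]
    tot_all <- tot_all + sh * an
    heat_all <- heat_all + sh * an_heat
    series[[a]] <- mk_rows(an, an_heat, a)
  }
  series[["all"]] <- mk_rows(tot_all, heat_all, "all")

  annual_an <- colSums(tot_all) / n_years
  annual_heat <- colSums(heat_all) / n_years
  cell_stats <- data.frame(
    cell = inc,
    stratum = c(rep("urban", length(u)), rep("rural", length(r))),
    annual_an = annual_an,
    annual_an_heat = annual_heat,
    annual_an_cold = annual_an - annual_heat)
  if (length(heat_idx)) {
    cell_stats$heat_ext_an <-
      colMeans(tot_all[heat_idx, , drop = FALSE])
    cell_stats$cold_ext_an <-
      colMeans(tot_all[cold_idx, , drop = FALSE])
  }

  structure(list(series = do.call(rbind, series), cell_stats = cell_stats,
                 mmt = mmts, dates = dates, n_years = n_years,
                 classification = classification),
            class = "daily_attribution")
}
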