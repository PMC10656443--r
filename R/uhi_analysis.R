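# Urban-minus-rural impact analysis: daily differentials, temporal
# aggregation (annual / meteorological seasons / extreme days), the
# imperviousness gradient, age standardization, exposure bias, climate
# grouping, city-metric correlations, and Monte-Carlo confidence intervals
# from the ERF uncertainty ensembles.

season_of <- function(dates) {
  m <- as.integer(format(dates, "%m"))
  c("DJF", "DJF", "MAM", "MAM", "MAM", "JJA",
    "JJA", "JJA", "SON", "SON", "SON", "DJF")[m]
}

#' Daily urban-minus-rural impact differentials
#'
#' Differences the unweighted urban and rural daily mean attributable numbers
#' of a [attribute_city()] result, per age group and component (total, heat,
#' cold), in deaths per 100k per day.
#'
#' @param attribution A `daily_attribution`.
#' @return Data frame (`impact_series`): one row per date x age group with
#'   urban/rural means and `diff_total`, `diff_heat`, `diff_cold`.
#' @export
daily_differential <- function(attribution) {
  stopifnot(inherits(attribution, "daily_attribution"))
  s <- attribution$series
  s$diff_total <- s$urban_total - s$rural_total
  s$diff_heat <- s$urban_heat - s$rural_heat
  # exact partition: cold differential is total minus heat
  s$diff_cold <- s$diff_total - s$diff_heat
  class(s) <- c("impact_series", "data.frame")
  s
}

#' Aggregate an impact series over periods
#'
#' Annual net impact is the mean over calendar years of the yearly sum of
#' daily differentials (deaths per 100k per year), with exact heat/cold
#' components. Seasonal values are per-day means over meteorological seasons
#' (DJF/MAM/JJA/SON, pooled across years by month). Extreme-day values are
#' per-day means over the heat/cold extreme day sets, with the percent change
#' relative to the rural mean on those days (`NA` if the rural mean is 0).
#'
#' @param series An impact series from [daily_differential()].
#' @param extremes A [find_extreme_days()] result.
#' @param age_group Which age group's rows to aggregate (default `"all"`).
#' @return One-row data frame (`impact_summary`).
#' @export
aggregate_periods <- function(series, extremes, age_group = "all") {
  s <- series[series$age_group == age_group, ]
  if (nrow(s) == 0L) stop("no rows for age group ", age_group)
  yrs <- format(s$date, "%Y")
  n_years <- length(unique(yrs))
  annual <- function(x) sum(x) / n_years
  out <- data.frame(
    age_group = age_group,
    annual_net = annual(s$diff_total),
    annual_heat = annual(s$diff_heat),
    annual_cold = annual(s$diff_cold))
  seas <- season_of(s$date)
  for (ss in c("DJF", "MAM", "JJA", "SON")) {
    out[[paste0("season_", ss)]] <- mean(s$diff_total[seas == ss])
  }
  for (set in c("heat", "cold")) {
    days <- if (set == "heat") extremes$heat_days else extremes$cold_days
    i <- s$date %in% days
    if (!any(i)) stop("extreme ", set, " days missing from the series")
    um <- mean(s$urban_total[i])
    rm_ <- mean(s$rural_total[i])
    out[[paste0(set, "_ext_mean")]] <- um - rm_
    out[[paste0(set, "_ext_pct_vs_rural")]] <-
      if (rm_ == 0) NA_real_ else 100 * (um - rm_) / rm_
  }
  class(out) <- c("impact_summary", "data.frame")
  out
}

#' Annual urban-minus-rural differential per age group
#'
#' Per-age annual net/heat/cold differentials (deaths per 100k per year),
#' the inputs to years-of-life-lost accounting and age standardization.
#'
#' @param series An impact series from [daily_differential()].
#' @return Data frame with one row per age group.
#' @export
annual_differential_by_age <- function(series) {
  do.call(rbind, lapply(AGE_GROUPS, function(a) {
    aggregate_periods(series,
                      extremes = list(heat_days = series$date[1],
                                      cold_days = series$date[1]),
                      age_group = a)[, c("age_group", "annual_net",
                                         "annual_heat", "annual_cold")]
  }))
}

#' Impact differential along the imperviousness gradient
#'
#' Bins included cells by the difference between their imperviousness and the
#' rural-mean imperviousness, and averages a per-cell impact aggregate within
#' each bin, expressed relative to the rural mean of the same aggregate.
#' Empty bins are absent (not zero).
#'
#' @param cell_values Per-cell impact aggregate (e.g. `annual_an` or
#'   `heat_ext_an` from `cell_stats`), aligned with `cells`.
#' @param cells Flat indices the values belong to.
#' @param imperviousness imperviousness_pct [static_layer()].
#' @param mask An [build_analysis_mask()] result.
#' @param bin_width Bin width in percentage points (default 5).
#' @return Data frame `bin_left`, `bin_mid`, `n_cells`, `mean_diff`, with
#'   attributes `max_delta_imperv` and `rural_mean_imperv`.
#' @export
imperviousness_profile <- function(cell_values, cells, imperviousness, mask,
                                   bin_width = 5) {
  rur <- mask_cells(mask, "rural")
  if (length(rur) == 0L) stop("rural stratum is empty")
  imp <- imperviousness$values
  rural_imp <- mean(imp[rur])
  rural_val <- mean(cell_values[cells %in% rur])
  delta <- imp[cells] - rural_imp
  bin <- floor(delta / bin_width) * bin_width
  agg <- stats::aggregate(
    data.frame(mean_diff = cell_values - rural_val, n_cells = 1),
    by = list(bin_left = bin),
    FUN = sum)
  agg$mean_diff <- agg$mean_diff / agg$n_cells
  out <- data.frame(bin_left = agg$bin_left,
                    bin_mid = agg$bin_left + bin_width / 2,
                    n_cells = agg$n_cells, mean_diff = agg$mean_diff)
  out <- out[order(out$bin_left), ]
  rownames(out) <- NULL
  attr(out, "max_delta_imperv") <- max(delta)
  attr(out, "rural_mean_imperv") <- rural_imp
  out
}

#' Cohort-level imperviousness gradient curves
#'
#' Pools per-city profiles into climate-group medians per bin. Cities whose
#' maximum urban-rural imperviousness difference is below `min_max_delta`
#' (default 80 percentage points) are excluded, and group medians supported by
#' fewer than `min_cities` cities in a bin are suppressed (`NA`).
#'
#' @param profiles Named list of [imperviousness_profile()] results.
#' @param groups Named character vector: climate group per city.
#' @param min_max_delta City filter threshold on max delta-imperviousness.
#' @param min_cities Minimum cities per (group, bin) for a median.
#' @return Data frame `group`, `bin_left`, `n_cities`, `median_diff`, with
#'   attribute `cities_used`.
#' @export
cohort_profile <- function(profiles, groups, min_max_delta = 80,
                           min_cities = 4) {
  keep <- names(profiles)[vapply(profiles, function(p) {
    attr(p, "max_delta_imperv") >= min_max_delta
  }, NA)]
  long <- do.call(rbind, lapply(keep, function(id) {
    cbind(city = id, group = unname(groups[[id]]), profiles[[id]])
  }))
  if (is.null(long)) {
    return(structure(data.frame(group = character(), bin_left = numeric(),
                                n_cities = integer(), median_diff = numeric()),
                     cities_used = character()))
  }
  agg <- stats::aggregate(long$mean_diff,
                          by = list(group = long$group,
                                    bin_left = long$bin_left),
                          FUN = function(x) c(n = length(x),
                                              med = stats::median(x)))
  out <- data.frame(group = agg$group, bin_left = agg$bin_left,
                    n_cities = as.integer(agg$x[, "n"]),
                    median_diff = agg$x[, "med"])
  out$median_diff[out$n_cities < min_cities] <- NA_real_
  out <- out[order(out$group, out$bin_left), ]
  rownames(out) <- NULL
  attr(out, "cities_used") <- keep
  out
}

#' Most- vs least-built-up risk differential
#'
#' Difference in the mean per-cell impact aggregate between highly sealed
#' (`>= hi`% imperviousness) and nearly unsealed (`<= lo`%) included cells,
#' with the percent change relative to the unsealed stratum. Returns `NA`
#' values (with a diagnostic attribute) when either stratum is empty.
#'
#' @param cell_values Per-cell impact aggregate (typically the heat-extreme
#'   day mean, `heat_ext_an`), aligned with `cells`.
#' @param cells Flat cell indices.
#' @param imperviousness imperviousness_pct [static_layer()].
#' @param hi,lo Imperviousness thresholds (default 90 / 10).
#' @return One-row data frame `diff`, `pct`, `n_hi`, `n_lo`.
#' @export
builtup_differential <- function(cell_values, cells, imperviousness,
                                 hi = 90, lo = 10) {
  imp <- imperviousness$values[cells]
  i_hi <- imp >= hi
  i_lo <- imp <= lo
  if (!any(i_hi) || !any(i_lo)) {
    out <- data.frame(diff = NA_real_, pct = NA_real_,
                      n_hi = sum(i_hi), n_lo = sum(i_lo))
    attr(out, "diagnostic") <- "empty built-up or unsealed stratum"
    return(out)
  }
  m_hi <- mean(cell_values[i_hi])
  m_lo <- mean(cell_values[i_lo])
  data.frame(diff = m_hi - m_lo,
             pct = if (m_lo == 0) NA_real_ else 100 * (m_hi - m_lo) / m_lo,
             n_hi = sum(i_hi), n_lo = sum(i_lo))
}

#' Age-standardize per-age impact summaries
#'
#' Re-weights per-age per-100k results with a standard age structure (the
#' 2013 European standard population by default) instead of the local one.
#' With `standard` equal to the local structure the result is unchanged.
#'
#' @param per_age_values Named numeric, per-100k value per age group.
#' @param standard Named standard shares (default [esp2013_shares()]).
#' @return Scalar standardized all-adult value.
#' @export
age_standardize <- function(per_age_values, standard = esp2013_shares()) {
  if (!setequal(names(per_age_values), AGE_GROUPS) ||
      !all(AGE_GROUPS %in% names(standard))) {
    stop("all five adult age groups are required")
  }
  aggregate_ages(per_age_values, standard[names(per_age_values)])
}

#' 2013 European standard population adult shares
#'
#' Shares of the five adult age groups under the 2013 European standard
#' population, read from the packaged weight table
#' (`inst/extdata/esp2013_adult_weights.csv`).
#'
#' @return Named shares summing to 1.
#' @export
esp2013_shares <- function() {
  path <- system.file("extdata", "esp2013_adult_weights.csv",
                      package = "uhimort", mustWork = TRUE)
  df <- utils::read.csv(path, comment.char = "#")
  stats::setNames(df$weight_per_100k / sum(df$weight_per_100k), df$age_group)
}

#' Exposure bias from population-weighted urban averaging
#'
#' The headline estimates average urban cells unweighted (each location counts
#' equally - the individual-inhabitant perspective). Because population
#' concentrates where imperviousness (and hence UHI) is high, weighting by
#' population instead shifts the urban mean; this returns that shift in
#' percent: `100 x (pop-weighted mean - unweighted mean) / unweighted mean`
#' of the per-cell impact aggregate over urban cells.
#'
#' @param cell_values Per-cell impact aggregate over the relevant day set
#'   (e.g. `heat_ext_an`), aligned with `cells`.
#' @param cells Flat cell indices.
#' @param population population_count [static_layer()].
#' @param mask An [build_analysis_mask()] result.
#' @return Percent bias (`NA` if the unweighted mean is 0).
#' @export
exposure_bias <- function(cell_values, cells, population, mask) {
  u <- mask_cells(mask, "urban")
  i <- cells %in% u
  if (!any(i)) stop("no urban cells among the supplied aggregates")
  w <- population$values[cells[i]]
  if (sum(w) <= 0) stop("urban population is zero")
  v <- cell_values[i]
  uw <- mean(v)
  pw <- sum(w * v) / sum(w)
  if (uw == 0) return(NA_real_)
  100 * (pw - uw) / uw
}

# human-readable base-class names for Koppen-Geiger first letters
KOPPEN_BASE <- c(A = "Tropical", B = "Arid", C = "Temperate",
                 D = "Continental", E = "Polar")

#' Group cities by Koppen-Geiger class, merging singletons
#'
#' Climate groups with a single city are merged into the group sharing their
#' first-letter base class with the most second/third-letter agreement
#' (largest group breaks remaining ties), and the merged group is relabelled
#' by the common base classification (e.g. a lone BWh city joining six BSk
#' cities forms an "Arid" group of seven). A singleton with no same-base
#' group keeps its base-class label and is flagged.
#'
#' @param labels Named character vector of Koppen-Geiger classes per city.
#' @return Data frame `city`, `koppen`, `group` with attribute
#'   `unmerged_singletons`.
#' @export
assign_climate_groups <- function(labels) {
  if (anyNA(labels) || any(!nzchar(labels))) stop("every city must be labelled")
  group <- stats::setNames(as.character(labels), names(labels))
  tab <- table(labels)
  singles <- names(tab)[tab == 1]
  flagged <- character(0)
  for (s in singles) {
    others <- setdiff(names(tab)[tab > 1], s)
    same_base <- others[substr(others, 1, 1) == substr(s, 1, 1)]
    if (length(same_base) == 0L) {
      group[labels == s] <- KOPPEN_BASE[[substr(s, 1, 1)]]
      flagged <- c(flagged, s)
      next
    }
    agree <- vapply(same_base, function(o) {
      sum(substring(o, 2:3, 2:3) == substring(s, 2:3, 2:3), na.rm = TRUE)
    }, 0)
    target <- same_base[order(-agree, -tab[same_base])][1]
    base_name <- KOPPEN_BASE[[substr(s, 1, 1)]]
    group[labels %in% c(s, target)] <- base_name
  }
  out <- data.frame(city = if (is.null(names(labels)))
                             seq_along(labels) else names(labels),
                    koppen = as.character(labels),
                    group = unname(group), row.names = NULL)
  attr(out, "unmerged_singletons") <- flagged
  out
}

#' Spearman correlation matrix between city metrics and impacts
#'
#' Two-sided Spearman rank correlations between each city-characteristic
#' column and each impact column, with p-values (exact permutation null for
#' n <= 9 without ties, large-sample approximation otherwise). Entries with
#' `p >= alpha` (default 0.01, i.e. 99% significance) are masked; constant
#' columns are masked with a diagnostic.
#'
#' @param metrics Data frame of city characteristics (numeric columns).
#' @param impacts Data frame of impact summaries (numeric columns), same row
#'   order (one row per city).
#' @param alpha Significance threshold for masking.
#' @return Long data frame `metric`, `impact`, `rho`, `p`, `shown`, `note`.
#' @export
correlation_matrix <- function(metrics, impacts, alpha = 0.01) {
  if (nrow(metrics) != nrow(impacts)) stop("row counts differ")
  if (nrow(metrics) < 5L) stop("need >= 5 cities")
  n <- nrow(metrics)
  out <- list()
  for (m in names(metrics)) {
    for (i in names(impacts)) {
      x <- metrics[[m]]
      y <- impacts[[i]]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        out[[length(out) + 1L]] <- data.frame(
          metric = m, impact = i, rho = NA_real_, p = NA_real_,
          shown = FALSE, note = "constant column")
        next
      }
      ct <- suppressWarnings(
        stats::cor.test(x, y, method = "spearman", exact = n <= 9))
      out[[length(out) + 1L]] <- data.frame(
        metric = m, impact = i, rho = unname(ct$estimate),
        p = ct$p.value, shown = ct$p.value < alpha, note = "")
    }
  }
  do.call(rbind, out)
}

#' City metrics table for correlation analysis
#'
#' Assembles the characteristics examined against the impact rankings: RR at
#' the observed extremes, warm days per year (days above the 65-74 MMT),
#' mean UHI magnitude (all-day urban-minus-rural temperature), the 85+/20-44
#' population ratio, and the annual mean temperature.
#'
#' @param city A `synthetic_city` (or compatible list).
#' @param mask An [build_analysis_mask()] result.
#' @param attribution The city's [attribute_city()] result.
#' @param extremes A [find_extreme_days()] result.
#' @return One-row data frame.
#' @export
city_metrics <- function(city, mask, attribution, extremes) {
  erf65 <- city$erfs[["65-74"]]$central
  dom <- extremes$domain_series
  n_years <- attribution$n_years
  u <- mask_cells(mask, "urban")
  r <- mask_cells(mask, "rural")
  uhi <- mean(colMeans(city$cube$values[, u, drop = FALSE])) -
    mean(colMeans(city$cube$values[, r, drop = FALSE]))
  pops <- stats::setNames(city$demography$population, city$demography$age_group)
  rrs <- sapply(AGE_GROUPS, function(a) extreme_rrs(city$erfs[[a]]$central))
  data.frame(
    rr_tmax = mean(rrs["rr_tmax", ]),
    rr_tmin = mean(rrs["rr_tmin", ]),
    warm_days_per_year = sum(dom$tmean_c > erf65$mmt) / n_years,
    mean_uhi = uhi,
    age_ratio = unname(pops[["85+"]] / pops[["20-44"]]),
    t_avg = mean(dom$tmean_c))
}

#' Monte-Carlo confidence summary across ERF draws
#'
#' Computes a cohort summary per uncertainty draw and returns the empirical
#' confidence interval across draws around the central-curve estimate.
#' Supported summaries: `"median"` (median impact across cities) and
#' `"adverse_count"` (number of cities with a positive annual net
#' differential, i.e. where the UHI is adverse).
#'
#' @param draw_values Matrix, `n_draws x n_cities`, of per-draw per-city
#'   results (e.g. annual net differentials).
#' @param central Numeric, length `n_cities`, from the central curves.
#' @param level Confidence level in `(0, 1)` (default 0.95; 0.90 is used for
#'   the adverse-city count).
#' @param summary `"median"` or `"adverse_count"`.
#' @return List `central`, `lower`, `upper`, `level`, `draw_summaries`.
#' @export
mc_confidence <- function(draw_values, central,
                          level = 0.95,
                          summary = c("median", "adverse_count")) {
  summary <- match.arg(summary)
  if (level <= 0 || level >= 1) stop("level must lie in (0, 1)")
  draw_values <- as.matrix(draw_values)
  if (ncol(draw_values) != length(central)) {
    stop("draws and central estimates disagree on the number of cities")
  }
  if (nrow(draw_values) < 2L && level < 1) {
    warning("fewer than 2 draws: interval has zero width")
  }
  f <- switch(summary,
              median = function(x) stats::median(x),
              adverse_count = function(x) sum(x > 0))
  s <- apply(draw_values, 1L, f)
  q <- stats::quantile(s, c((1 - level) / 2, 1 - (1 - level) / 2),
                       names = FALSE, type = 7)
  list(central = f(central), lower = q[1], upper = q[2], level = level,
       draw_summaries = s)
}

# --- draw-level impact engine ---------------------------------------------

# Weighted temperature histograms per stratum x period for one city.
# Aggregating AF over a fine temperature histogram (default 0.02 degC bins)
# turns the per-draw cost from O(cells x days) into O(bins); the central
# estimates use the exact per-cell engine.
stratum_histograms <- function(cube, mask, extremes, bin_width = 0.02) {
  dates <- cube$dates
  diy <- days_in_year_of(dates)
  n_years <- length(unique(format(dates, "%Y")))
  day_sets <- list(
    annual = seq_along(dates),
    heat_ext = match(extremes$heat_days, dates),
    cold_ext = match(extremes$cold_days, dates))
  out <- list(bin_width = bin_width, n_years = n_years)
  for (stratum in c("urban", "rural")) {
    idx <- mask_cells(mask, stratum)
    Tm <- cube$values[, idx, drop = FALSE]
    for (set in names(day_sets)) {
      d <- day_sets[[set]]
      tv <- as.vector(Tm[d, , drop = FALSE])
      # weights fold in the per-day 1/days_in_year AN conversion, so that
      # sum(w * AF * rate) is the per-year (annual) or per-day (extreme) value
      w <- if (set == "annual") {
        rep(1 / (diy[d] * n_years * length(idx)), times = length(idx))
      } else {
        rep(1 / (diy[d] * length(d) * length(idx)), times = length(idx))
      }
      bins <- round(tv / bin_width)
      sums <- rowsum(w, bins)
      out[[paste(stratum, set, sep = ".")]] <- list(
        t = as.numeric(rownames(sums)) * bin_width, w = sums[, 1L])
    }
  }
  out
}

# Per-draw city summaries from histograms: annual net / heat / cold
# differentials plus extreme-day means, for one ERF draw index (0 = central).
draw_city_summary <- function(hists, erfs, baseline, age_structure, draw) {
  get_curve <- function(ens) if (draw == 0) ens$central else ens$draws[[draw]]
  acc <- c(annual_net = 0, annual_heat = 0, annual_cold = 0,
           heat_ext_mean = 0, cold_ext_mean = 0)
  for (a in AGE_GROUPS) {
    curve <- get_curve(erfs[[a]])
    sh <- age_structure[[a]]
    rate <- baseline[[a]]
    for (set in c("annual", "heat_ext", "cold_ext")) {
      hu <- hists[[paste0("urban.", set)]]
      hr <- hists[[paste0("rural.", set)]]
      af_u <- attributable_fraction(evaluate_rr(curve, hu$t))
      af_r <- attributable_fraction(evaluate_rr(curve, hr$t))
      if (set == "annual") {
        # weights already include 1/days_in_year and 1/n_years
        tot <- sum(hu$w * af_u) - sum(hr$w * af_r)
        warm_u <- hu$t > curve$mmt
        warm_r <- hr$t > curve$mmt
        heat <- sum(hu$w[warm_u] * af_u[warm_u]) -
          sum(hr$w[warm_r] * af_r[warm_r])
        acc["annual_net"] <- acc["annual_net"] + sh * rate * tot
        acc["annual_heat"] <- acc["annual_heat"] + sh * rate * heat
        acc["annual_cold"] <- acc["annual_cold"] + sh * rate * (tot - heat)
      } else {
        val <- (sum(hu$w * af_u) - sum(hr$w * af_r)) * rate
        acc[paste0(sub("_ext", "", set), "_ext_mean")] <-
          acc[paste0(sub("_ext", "", set), "_ext_mean")] + sh * val
      }
    }
  }
  acc
}

#' Per-draw impact summaries for a city
#'
#' Evaluates the urban-minus-rural impact differentials for every ERF
#' uncertainty draw of a city, using a fine temperature-histogram aggregation
#' (bin width `bin_width` degrees C) per stratum and period. Returns a matrix
#' with one row per draw; row `"central"` holds the central-curve result.
#'
#' @param city A `synthetic_city` (or list with `cube`, `erfs`, `baseline`,
#'   `demography`).
#' @param mask An [build_analysis_mask()] result.
#' @param extremes A [find_extreme_days()] result.
#' @param bin_width Histogram bin width, degrees C.
#' @return Matrix `(n_draws + 1) x 5` with columns `annual_net`,
#'   `annual_heat`, `annual_cold`, `heat_ext_mean`, `cold_ext_mean`; first
#'   row is the central estimate.
#' @export
impact_by_draw <- function(city, mask, extremes, bin_width = 0.02) {
  hists <- stratum_histograms(city$cube, mask, extremes, bin_width)
  baseline <- stats::setNames(city$baseline$annual_deaths_per_100k,
                              city$baseline$age_group)
  shares <- stats::setNames(city$demography$share, city$demography$age_group)
  n_draws <- length(city$erfs[[1]]$draws)
  out <- t(vapply(0:n_draws, function(d) {
    draw_city_summary(hists, city$erfs, baseline, shares, d)
  }, numeric(5)))
  rownames(out) <- c("central", paste0("draw_", seq_len(n_draws)))
  out
}
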