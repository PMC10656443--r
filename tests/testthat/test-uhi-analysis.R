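# Urban-minus-rural differentials, period aggregation, gradient profiles,
# standardization, climate grouping, correlations and MC intervals.

# two-cell city: one urban cell a fixed offset above one rural cell
two_cell_city <- function(urban_t, rural_t, dates, rate = 365) {
  spec <- grid_spec(1, 2)
  layers <- list(
    land_class = static_layer(spec, "land_class", c("urban", "rural")),
    elevation = static_layer(spec, "elevation_m", c(0, 0)),
    population = static_layer(spec, "population_count", c(1, 1)))
  mask <- build_analysis_mask(layers$land_class, layers$elevation,
                              layers$population)
  cube <- temperature_cube(spec, dates, cbind(urban_t, rural_t))
  list(spec = spec, layers = layers, mask = mask, cube = cube)
}

test_that("the daily differential reproduces Eq.-1 hand arithmetic", {
  # urban at MMT+2 with RR 1.5, rural at the MMT: AF = 1/3, baseline
  # 365/100k/yr over a 365-day year -> differential 1/3 per 100k per day
  dates <- as.Date("2015-07-01")
  tc <- two_cell_city(20, 18, dates)
  # a curve with RR(20) = 1.5 exactly: linear warm limb to RR 1.5 at 20
  curve <- erf_curve(c(5, 18, 20), c(log(1.2), 0, log(1.5)),
                     c(5, 20), "65-74", interpolation = "linear")
  erfs <- stats::setNames(lapply(AGE_GROUPS, function(a) {
    c2 <- curve; c2$age_group <- a; c2
  }), AGE_GROUPS)
  att <- attribute_city(tc$cube, tc$mask, erfs, flat_baseline(365),
                        equal_shares())
  s <- daily_differential(att)
  all_row <- s[s$age_group == "all", ]
  expect_equal(all_row$urban_total, 1 / 3, tolerance = 1e-12)
  expect_equal(all_row$rural_total, 0, tolerance = 1e-12)
  expect_equal(all_row$diff_total, 1 / 3, tolerance = 1e-12)
  expect_equal(all_row$diff_heat, 1 / 3, tolerance = 1e-12)
  expect_equal(all_row$diff_cold, 0, tolerance = 1e-12)
})

test_that("swapping urban and rural labels negates every differential", {
  city <- small_city(seed = 23, n = 10, n_draws = 1, end = "2016-03-31")
  mask <- build_analysis_mask(city$layers$land_class, city$layers$elevation,
                              city$layers$population)
  baseline <- stats::setNames(city$baseline$annual_deaths_per_100k,
                              city$baseline$age_group)
  shares <- stats::setNames(city$demography$share, city$demography$age_group)
  s1 <- daily_differential(
    attribute_city(city$cube, mask, city$erfs, baseline, shares))
  swapped <- mask
  swapped$status <- c(urban_included = "rural_included",
                      rural_included = "urban_included",
                      excluded_water = "excluded_water",
                      excluded_elevation = "excluded_elevation")[mask$status]
  s2 <- daily_differential(
    attribute_city(city$cube, swapped, city$erfs, baseline, shares))
  for (col in c("diff_total", "diff_heat", "diff_cold")) {
    expect_equal(s2[[col]], -s1[[col]], tolerance = 1e-12)
  }
})

test_that("impacts scale linearly with baseline mortality", {
  city <- small_city(seed = 24, n = 10, n_draws = 1, end = "2016-03-31")
  mask <- build_analysis_mask(city$layers$land_class, city$layers$elevation,
                              city$layers$population)
  baseline <- stats::setNames(city$baseline$annual_deaths_per_100k,
                              city$baseline$age_group)
  shares <- stats::setNames(city$demography$share, city$demography$age_group)
  ext <- find_extreme_days(city$cube, city$layers$population, mask)
  s1 <- aggregate_periods(daily_differential(
    attribute_city(city$cube, mask, city$erfs, baseline, shares)), ext)
  s3 <- aggregate_periods(daily_differential(
    attribute_city(city$cube, mask, city$erfs, 3 * baseline, shares)), ext)
  for (col in c("annual_net", "annual_heat", "annual_cold", "heat_ext_mean")) {
    expect_equal(s3[[col]], 3 * s1[[col]], tolerance = 1e-9)
  }
  # valuation inherits the scaling
  expect_equal(vsl_impact(3 * s1$annual_net, 2e6),
               3 * vsl_impact(s1$annual_net, 2e6))
})

test_that("period aggregation matches direct summation oracles", {
  dates <- seq(as.Date("2015-01-01"), as.Date("2015-12-31"), by = "day")
  n <- length(dates)
  tc <- two_cell_city(rep(19, n), rep(18, n), dates)
  curve <- erf_curve(c(5, 18, 20), c(log(1.2), 0, log(1.5)), c(5, 20),
                     "65-74", interpolation = "linear")
  erfs <- stats::setNames(lapply(AGE_GROUPS, function(a) {
    c2 <- curve; c2$age_group <- a; c2
  }), AGE_GROUPS)
  att <- attribute_city(tc$cube, tc$mask, erfs, flat_baseline(365),
                        equal_shares())
  s <- daily_differential(att)
  ext <- find_extreme_days(tc$cube, tc$layers$population, tc$mask,
                           fraction = 0.02)
  out <- aggregate_periods(s, ext)
  d <- s$diff_total[s$age_group == "all"][1]
  # constant differential d on a 365-day year: annual net is 365 d
  expect_equal(out$annual_net, 365 * d, tolerance = 1e-9)
  expect_equal(out$season_JJA, d, tolerance = 1e-12)
  expect_equal(out$heat_ext_mean, d, tolerance = 1e-12)
  # rural mean AN is zero on extreme days -> percent flagged missing
  expect_true(is.na(out$heat_ext_pct_vs_rural))
})

test_that("annual net equals the sum of seasonal contributions", {
  city <- small_city(seed = 25, n = 10, n_draws = 1)
  res <- analyse_city(city)
  s <- res$series[res$series$age_group == "all", ]
  seas <- c("DJF", "MAM", "JJA", "SON")
  m <- as.integer(format(s$date, "%m"))
  lab <- c("DJF", "DJF", "MAM", "MAM", "MAM", "JJA", "JJA", "JJA", "SON",
           "SON", "SON", "DJF")[m]
  total_by_season <- vapply(seas, function(x) sum(s$diff_total[lab == x]), 0)
  n_years <- length(unique(format(s$date, "%Y")))
  expect_equal(sum(total_by_season) / n_years, res$summary$annual_net,
               tolerance = 1e-9)
  # percent and absolute extreme-day views agree
  heat <- s[s$date %in% res$extremes$heat_days, ]
  expect_equal(res$summary$heat_ext_pct_vs_rural,
               100 * (mean(heat$urban_total) - mean(heat$rural_total)) /
                 mean(heat$rural_total),
               tolerance = 1e-9)
})

test_that("imperviousness profiles recover stratified means", {
  spec <- grid_spec(2, 2)
  layers <- list(
    land_class = static_layer(spec, "land_class",
                              c("urban", "urban", "rural", "rural")),
    elevation = static_layer(spec, "elevation_m", rep(0, 4)),
    population = static_layer(spec, "population_count", rep(1, 4)))
  mask <- build_analysis_mask(layers$land_class, layers$elevation,
                              layers$population)
  imp <- static_layer(spec, "imperviousness_pct", c(90, 60, 10, 0))
  cells <- mask_cells(mask, "all")
  vals <- c(0.9, 0.5, 0.12, 0.08)  # aligned with cells 1..4
  prof <- imperviousness_profile(vals, cells, imp, mask, bin_width = 5)
  rural_imp <- 5
  rural_val <- 0.1
  expect_equal(attr(prof, "rural_mean_imperv"), rural_imp)
  expect_equal(attr(prof, "max_delta_imperv"), 85)
  # two urban bins at delta 85 and 55, rural cells at delta 5 and -5
  expect_equal(prof$mean_diff[prof$bin_left == 85], 0.9 - rural_val)
  expect_equal(prof$mean_diff[prof$bin_left == 55], 0.5 - rural_val)
  # rural deltas are +5 and -5: left-closed bins put them at 5 and -5
  expect_equal(sort(prof$bin_left), c(-5, 5, 55, 85))
})

test_that("uniform-imperviousness domains give a single zero bin", {
  spec <- grid_spec(1, 4)
  layers <- list(
    land_class = static_layer(spec, "land_class",
                              c("urban", "urban", "rural", "rural")),
    elevation = static_layer(spec, "elevation_m", rep(0, 4)),
    population = static_layer(spec, "population_count", rep(1, 4)))
  mask <- build_analysis_mask(layers$land_class, layers$elevation,
                              layers$population)
  imp <- static_layer(spec, "imperviousness_pct", rep(40, 4))
  prof <- imperviousness_profile(rep(0.3, 4), mask_cells(mask, "all"), imp,
                                 mask)
  expect_identical(nrow(prof), 1L)
  expect_equal(prof$bin_left, 0)
  expect_equal(prof$mean_diff, 0)
})

test_that("cohort profiles filter shallow cities and thin medians", {
  mk <- function(max_delta) {
    p <- data.frame(bin_left = c(0, 40), bin_mid = c(2.5, 42.5),
                    n_cells = c(4, 4), mean_diff = c(0, 0.2))
    attr(p, "max_delta_imperv") <- max_delta
    p
  }
  profiles <- list(a = mk(85), b = mk(90), c = mk(95), d = mk(99),
                   e = mk(60), f = mk(30))
  groups <- c(a = "Temperate", b = "Temperate", c = "Temperate",
              d = "Temperate", e = "Temperate", f = "Temperate")
  out <- cohort_profile(profiles, groups)
  # cities below the 80-point span filter are dropped
  expect_setequal(attr(out, "cities_used"), c("a", "b", "c", "d"))
  expect_true(all(is.finite(out$median_diff[out$n_cities >= 4])))
  # with only 3 qualifying cities the medians are suppressed
  out3 <- cohort_profile(profiles[1:4][-1], groups)
  expect_true(all(is.na(out3$median_diff)))
})

test_that("built-up differential compares sealed against unsealed cells", {
  spec <- grid_spec(1, 4)
  imp <- static_layer(spec, "imperviousness_pct", c(95, 92, 5, 8))
  vals <- c(0.5, 0.4, 0.1, 0.2)
  out <- builtup_differential(vals, 1:4, imp)
  expect_equal(out$diff, 0.45 - 0.15)
  expect_equal(out$pct, 100 * 0.3 / 0.15)
  # no sealed cells: missing with a diagnostic
  imp2 <- static_layer(spec, "imperviousness_pct", c(50, 40, 5, 8))
  out2 <- builtup_differential(vals, 1:4, imp2)
  expect_true(is.na(out2$diff))
  expect_match(attr(out2, "diagnostic"), "empty")
})

test_that("age standardization is an identity under the local structure", {
  per_age <- stats::setNames(c(0.1, 0.4, 1.1, 2.4, 6), AGE_GROUPS)
  local <- stats::setNames(c(0.4, 0.3, 0.15, 0.1, 0.05), AGE_GROUPS)
  expect_equal(age_standardize(per_age, local),
               aggregate_ages(per_age, local))
  # equal per-age values are invariant under any weighting
  eq <- stats::setNames(rep(1.3, 5), AGE_GROUPS)
  expect_equal(age_standardize(eq, local), 1.3)
  expect_equal(age_standardize(eq, esp2013_shares()), 1.3)
  # two-group reweighting, hand computed
  v <- stats::setNames(c(1, 3, 0, 0, 0), AGE_GROUPS)
  std <- stats::setNames(c(0.5, 0.5, 0, 0, 0), AGE_GROUPS)
  expect_equal(age_standardize(v, std), 2)
  expect_error(age_standardize(per_age[-1], local), "age group")
})

test_that("ESP2013 adult shares load and normalize", {
  sh <- esp2013_shares()
  expect_setequal(names(sh), AGE_GROUPS)
  expect_equal(sum(sh), 1, tolerance = 1e-12)
  expect_equal(unname(sh["20-44"]), 32500 / 78500, tolerance = 1e-12)
})

test_that("exposure bias is zero for uniform population and positive when population tracks heat", {
  spec <- grid_spec(1, 4)
  layers <- list(
    land_class = static_layer(spec, "land_class", rep("urban", 4)),
    elevation = static_layer(spec, "elevation_m", rep(0, 4)),
    population = static_layer(spec, "population_count", rep(5, 4)))
  # need one rural cell for a valid mask; make cell 4 rural
  layers$land_class <- static_layer(spec, "land_class",
                                    c("urban", "urban", "urban", "rural"))
  mask <- build_analysis_mask(layers$land_class, layers$elevation,
                              layers$population)
  cells <- mask_cells(mask, "all")
  vals <- c(0.3, 0.2, 0.1, 0)
  expect_equal(exposure_bias(vals, cells, layers$population, mask), 0)
  # all population in the hottest cell: bias = 100 (max - mean) / mean
  pop2 <- static_layer(spec, "population_count", c(50, 0, 0, 0))
  expect_equal(exposure_bias(vals, cells, pop2, mask),
               100 * (0.3 - 0.2) / 0.2)
  # synthetic city with population-imperviousness coupling: positive bias on
  # heat-extreme days
  city <- small_city(seed = 26, n = 16, n_draws = 1)
  res <- analyse_city(city)
  bias <- exposure_bias(res$attribution$cell_stats$heat_ext_an,
                        res$attribution$cell_stats$cell,
                        city$layers$population, res$mask)
  expect_gt(bias, 0)
})

test_that("climate grouping merges singletons by base class", {
  labels <- stats::setNames(c("BWh", rep("BSk", 6)), paste0("c", 1:7))
  out <- assign_climate_groups(labels)
  expect_identical(unique(out$group), "Arid")
  expect_identical(nrow(out), 7L)

  # no singletons: unchanged
  labels2 <- stats::setNames(c("Cfb", "Cfb", "Dfb", "Dfb"), paste0("c", 1:4))
  out2 <- assign_climate_groups(labels2)
  expect_identical(out2$group, unname(labels2))

  # Csa singleton joins the Cfb group under the Temperate base label
  labels3 <- stats::setNames(c("Cfb", "Cfb", "Cfb", "Csa"), paste0("c", 1:4))
  out3 <- assign_climate_groups(labels3)
  expect_identical(unique(out3$group), "Temperate")

  # singleton with no same-base group keeps its base class and is flagged
  labels4 <- stats::setNames(c("ET", "Cfb", "Cfb"), paste0("c", 1:3))
  out4 <- assign_climate_groups(labels4)
  expect_identical(out4$group[1], "Polar")
  expect_identical(attr(out4, "unmerged_singletons"), "ET")
})

test_that("correlation matrix agrees with a brute-force rank oracle", {
  set.seed(33)
  n <- 6
  metrics <- data.frame(m1 = rnorm(n), m2 = runif(n))
  impacts <- data.frame(i1 = rnorm(n))
  impacts$i2 <- metrics$m1          # rho = 1
  impacts$i3 <- -metrics$m1         # rho = -1
  out <- correlation_matrix(metrics, impacts, alpha = 0.01)
  get <- function(m, i) out[out$metric == m & out$impact == i, ]
  expect_equal(get("m1", "i2")$rho, 1)
  expect_true(get("m1", "i2")$shown)
  expect_equal(get("m1", "i3")$rho, -1)
  # brute-force Spearman from rank Pearson
  brute <- cor(rank(metrics$m1), rank(impacts$i1))
  expect_equal(get("m1", "i1")$rho, brute, tolerance = 1e-12)
  # constant columns are masked with a note
  metrics$flat <- 1
  out2 <- correlation_matrix(metrics, impacts)
  flat_rows <- out2[out2$metric == "flat", ]
  expect_true(all(is.na(flat_rows$rho)))
  expect_true(all(!flat_rows$shown))
  expect_match(flat_rows$note[1], "constant")
  expect_error(correlation_matrix(metrics[1:4, ], impacts[1:4, ]), ">= 5")
})

test_that("Monte-Carlo summaries produce ordered empirical intervals", {
  draws <- matrix(rnorm(200 * 8), 200, 8)
  central <- rnorm(8)
  mc <- mc_confidence(draws, central, level = 0.9, summary = "median")
  expect_lte(mc$lower, mc$upper)
  expect_equal(mc$central, median(central))
  # degenerate ensemble: zero width at the central value
  dg <- matrix(rep(c(1, -2, 3, 0.5, -1, 2, 0, 1), each = 50), 50, 8)
  mcd <- mc_confidence(dg, dg[1, ], level = 0.9, summary = "median")
  expect_equal(mcd$lower, mcd$upper)
  expect_equal(mcd$lower, median(dg[1, ]))
  # adverse count: every draw 3 of 10 -> [3, 3]
  dv <- matrix(rep(c(rep(1, 3), rep(-1, 7)), each = 40), 40, 10)
  mca <- mc_confidence(dv, dv[1, ], level = 0.9, summary = "adverse_count")
  expect_equal(c(mca$lower, mca$upper), c(3, 3))
  expect_equal(mca$central, 3)
  expect_error(mc_confidence(draws, central, level = 1.2), "level")
})
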