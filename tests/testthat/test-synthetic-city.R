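# Synthetic-city generator: determinism, ground-truth features, ensemble
# statistics, cohort construction.

test_that("a zero-UHI city has identical urban and rural temperature series", {
  city <- small_city(seed = 2, n = 12, uhi_amplitude = 0, n_draws = 1)
  mask <- build_analysis_mask(city$layers$land_class, city$layers$elevation,
                              city$layers$population)
  u <- mask_cells(mask, "urban")
  r <- mask_cells(mask, "rural")
  urban <- rowMeans(city$cube$values[, u, drop = FALSE])
  rural <- rowMeans(city$cube$values[, r, drop = FALSE])
  expect_lt(max(abs(urban - rural)), 1e-12)
})

test_that("generation is deterministic for a fixed recipe", {
  rec <- city_recipe(n_rows = 10, n_cols = 10, seed = 42, n_draws = 2,
                     start_date = as.Date("2015-01-01"),
                     end_date = as.Date("2015-06-30"))
  a <- generate_city(rec)
  b <- generate_city(rec)
  expect_identical(a$cube$values, b$cube$values)
  expect_identical(a$layers$population$values, b$layers$population$values)
  expect_identical(a$erfs[["85+"]]$draws[[2]]$log_rr_at_knots,
                   b$erfs[["85+"]]$draws[[2]]$log_rr_at_knots)
  # and it does not disturb the caller's RNG
  set.seed(1); x <- rnorm(1)
  set.seed(1); generate_city(rec); y <- rnorm(1)
  expect_identical(x, y)
})

test_that("water placement matches the requested fraction exactly", {
  city <- small_city(seed = 5, n = 20, water_fraction = 0.1, n_draws = 1,
                     end = "2016-04-30")
  expect_identical(sum(city$layers$land_class$values == "water"),
                   as.integer(round(0.1 * 400)))
  expect_true(all(city$layers$population$values[
    city$layers$land_class$values == "water"] == 0))
})

test_that("a requested hill exceeds the elevation exclusion threshold", {
  city <- small_city(seed = 6, n = 16, hill_height_m = 150, n_draws = 1,
                     end = "2016-04-30")
  mask <- build_analysis_mask(city$layers$land_class, city$layers$elevation,
                              city$layers$population)
  expect_gt(sum(mask$status == "excluded_elevation"), 0)
  flat <- small_city(seed = 6, n = 16, hill_height_m = 0, n_draws = 1,
                     end = "2016-04-30")
  maskf <- build_analysis_mask(flat$layers$land_class, flat$layers$elevation,
                               flat$layers$population)
  expect_identical(sum(maskf$status == "excluded_elevation"), 0L)
})

test_that("population is rank-correlated with imperviousness at the target", {
  city <- small_city(seed = 9, n = 30, n_draws = 1, end = "2016-04-30")
  land <- city$layers$land_class$values != "water"
  rho <- suppressWarnings(cor(
    city$layers$imperviousness$values[land],
    city$layers$population$values[land], method = "spearman"))
  expect_lt(abs(rho - 0.47), 0.15)
})

test_that("temperatures stay inside the construction bound", {
  rec <- city_recipe(n_rows = 14, n_cols = 14, seed = 4, n_draws = 1)
  city <- generate_city(rec)
  upper <- rec$annual_mean_c + rec$seasonal_amplitude_c +
    8 * rec$weather_sd_c + rec$uhi_amplitude * (1 + rec$uhi_seasonal_modulation)
  lower <- rec$annual_mean_c - rec$seasonal_amplitude_c - 8 * rec$weather_sd_c
  expect_true(all(city$cube$values <= upper))
  expect_true(all(city$cube$values >= lower))
})

test_that("ensemble with zero coefficient sd collapses to the central curve", {
  params <- default_erf_params()
  set.seed(10)
  ref <- rnorm(400, 12, 7)
  ens <- generate_erf_ensemble(params, ref, n_draws = 4, coefficient_sd = 0,
                               seed = 77)
  for (a in AGE_GROUPS) {
    for (d in ens[[a]]$draws) {
      expect_equal(d$log_rr_at_knots, ens[[a]]$central$log_rr_at_knots,
                   tolerance = 1e-12)
      expect_equal(d$mmt, ens[[a]]$central$mmt, tolerance = 1e-12)
    }
  }
})

test_that("central curve carries the recipe's warm-end risk", {
  params <- default_erf_params()[3, ]  # 65-74
  params$log_rr_warm <- log(1.5)
  params$mmt_c <- 18
  set.seed(12)
  ref <- rnorm(500, 12, 7)
  ens <- generate_erf_ensemble(params, ref, n_draws = 1, coefficient_sd = 0,
                               seed = 3)
  curve <- ens[["65-74"]]$central
  # interpolation-level accuracy: recentring against the continuous minimum
  # moves the end points by the size of the cubic's undershoot (~1e-3)
  expect_equal(unname(extreme_rrs(curve)["rr_tmax"]), 1.5, tolerance = 5e-3)
  expect_lt(abs(curve$mmt - 18), 0.25)
})

test_that("draw spread recovers the stated coefficient sd", {
  params <- default_erf_params()[2, ]
  set.seed(14)
  ref <- rnorm(500, 12, 7)
  ens <- generate_erf_ensemble(params, ref, n_draws = 1000,
                               coefficient_sd = 0.05, seed = 5)
  warm_lrr <- vapply(ens[["45-64"]]$draws, function(d) {
    log(evaluate_rr(d, d$observed_range[2]))
  }, 0)
  expect_lt(abs(sd(warm_lrr) - 0.05) / 0.05, 0.10)
})

test_that("cohorts are deterministic with distinct per-city seeds", {
  arch <- list(city_archetype("Cfb", annual_mean_c = 11))
  co1 <- generate_multicity_cohort(3, arch, master_seed = 99, n_rows = 10,
                                   n_cols = 10, n_draws = 1,
                                   end_date = as.Date("2015-06-30"))
  co2 <- generate_multicity_cohort(3, arch, master_seed = 99, n_rows = 10,
                                   n_cols = 10, n_draws = 1,
                                   end_date = as.Date("2015-06-30"))
  expect_identical(lapply(co1, function(c) c$cube$values),
                   lapply(co2, function(c) c$cube$values))
  seeds <- vapply(co1, function(c) c$truth$seed, 0L)
  expect_identical(length(unique(seeds)), 3L)
  expect_identical(unique(vapply(co1, `[[`, "", "koppen")), "Cfb")
  expect_false(identical(co1[[1]]$cube$values, co1[[2]]$cube$values))
  expect_error(generate_multicity_cohort(2, list(), 1), "non-empty")
})

test_that("archetype annual means are realized in the long-run city mean", {
  archs <- list(city_archetype("Dfb", annual_mean_c = 5),
                city_archetype("Cfb", annual_mean_c = 12),
                city_archetype("Csa", annual_mean_c = 18))
  co <- generate_multicity_cohort(3, archs, master_seed = 17, n_rows = 12,
                                  n_cols = 12, n_draws = 1, uhi_amplitude = 0.5)
  realized <- vapply(co, function(c) mean(c$cube$values), 0)
  expect_true(all(abs(realized - c(5, 12, 18)) < 0.5))
})

test_that("recipes validate their invariants", {
  expect_error(city_recipe(uhi_amplitude = -1), "uhi_amplitude")
  bad_shares <- stats::setNames(c(0.4, 0.3, 0.2, 0.05, 0.02), AGE_GROUPS)
  expect_error(city_recipe(age_shares = bad_shares), "sum to 1")
  expect_error(city_recipe(weather_ar1 = 1), "weather_ar1")
  expect_error(city_recipe(n_draws = 0), "n_draws")
})
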