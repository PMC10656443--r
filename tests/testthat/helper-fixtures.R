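# Fixture builders shared across the suite. Everything is generated in code;
# fixtures are deliberately tiny.

# a flat 2x2 test domain: one urban, three rural cells, uniform population
tiny_domain <- function(elev = c(100, 100, 100, 100), pop = rep(10, 4),
                        class = c("urban", "rural", "rural", "rural"),
                        threshold = 100) {
  spec <- grid_spec(2, 2)
  layers <- list(
    land_class = static_layer(spec, "land_class", class),
    elevation = static_layer(spec, "elevation_m", elev),
    population = static_layer(spec, "population_count", pop))
  mask <- build_analysis_mask(layers$land_class, layers$elevation,
                              layers$population, threshold = threshold)
  list(spec = spec, layers = layers, mask = mask)
}

# V-shaped piecewise-linear ERF with known MMT and end risks
toy_curve <- function(mmt = 18, log_rr_cold = log(1.5), log_rr_warm = log(1.4),
                      t_lo = 5, t_hi = 30, age_group = "65-74",
                      interpolation = "linear") {
  erf_curve(c(t_lo, mmt, t_hi), c(log_rr_cold, 0, log_rr_warm),
            observed_range = c(t_lo, t_hi), age_group = age_group,
            interpolation = interpolation)
}

# identical toy curves for all five age groups
toy_erfs <- function(...) {
  out <- lapply(AGE_GROUPS, function(a) toy_curve(age_group = a, ...))
  names(out) <- AGE_GROUPS
  out
}

flat_baseline <- function(rate = 365) {
  stats::setNames(rep(rate, 5), AGE_GROUPS)
}

equal_shares <- function() stats::setNames(rep(0.2, 5), AGE_GROUPS)

# a small but fully featured synthetic city for integration-style tests
small_city <- function(seed = 7, n = 20, n_draws = 5,
                       start = "2016-01-01", end = "2016-12-31", ...) {
  generate_city(city_recipe(n_rows = n, n_cols = n, seed = seed,
                            n_draws = n_draws, start_date = as.Date(start),
                            end_date = as.Date(end), ...))
}
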