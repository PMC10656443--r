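# Synthetic-city generator: grids, climate, demography and ERF ensembles with
# known ground truth, so that every downstream stage is testable without the
# proprietary climate fields, register data or deposited curve sets.
#
# Temperature model: T(cell, d) = T_bg(d) + A * (imperviousness/100) * m(d)
#                                 + eps(d)
# with T_bg a sinusoidal seasonal cycle, m(d) a seasonal modulation of the
# urban heat island, A the UHI amplitude at 100% imperviousness, and eps an
# AR(1) weather anomaly shared across all cells (spatially uniform, so the
# UHI term is the only urban-rural temperature difference by construction).

# --- deterministic sub-seed derivation -------------------------------------

# stable 31-bit hash of (master seed, stream components); keeps derived seeds
# below 2^31 so they are valid R integer seeds
mix_seed <- function(master, ...) {
  parts <- unlist(lapply(list(master, ...), function(x) {
    if (is.character(x)) utf8ToInt(paste(x, collapse = "/")) else as.numeric(x)
  }))
  h <- 17
  m <- 2147483647
  for (p in parts) h <- (h * 31 + (p %% m) + 1) %% m
  as.integer(h)
}

# run code under a derived seed without disturbing the caller's RNG state
with_stream <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# --- recipe ----------------------------------------------------------------

#' Default ground-truth parameters of the synthetic city
#'
#' The study conditions baked into [city_recipe()]: age-group ERF shape
#' parameters (MMT falling and end-point risks rising with age), adult
#' age-structure shares, steeply age-graded annual baseline mortality per
#' 100k, and remaining life expectancy per age group.
#'
#' @return `default_erf_params()` a data frame; the others named numeric
#'   vectors keyed by age group.
#' @export
default_erf_params <- function() {
  data.frame(
    age_group = AGE_GROUPS,
    mmt_c = c(19, 18.5, 18, 17.5, 17),
    log_rr_cold = log(c(1.20, 1.35, 1.50, 1.70, 1.90)),
    log_rr_warm = log(c(1.15, 1.25, 1.40, 1.55, 1.70)),
    curvature = rep(1.5, 5L)
  )
}

#' @rdname default_erf_params
#' @export
default_age_shares <- function() {
  stats::setNames(c(0.40, 0.33, 0.13, 0.10, 0.04), AGE_GROUPS)
}

#' @rdname default_erf_params
#' @export
default_baseline_mortality <- function() {
  # annual all-cause deaths per 100k, steeply age-graded as in register data
  stats::setNames(c(80, 500, 1500, 4500, 14000), AGE_GROUPS)
}

#' @rdname default_erf_params
#' @export
default_life_expectancy <- function() {
  stats::setNames(c(50, 28, 16, 9, 4.5), AGE_GROUPS)
}

#' Synthetic city recipe
#'
#' Bundles every ground-truth parameter of a synthetic city: grid geometry,
#' background climate and UHI, imperviousness and population fields, adult
#' demography, baseline mortality, age-group ERF shape parameters and the
#' uncertainty-ensemble settings. The generated city records the recipe as its
#' `truth`, so analytic expectations can be computed from it cell by cell.
#'
#' @param n_rows,n_cols,cell_size Grid geometry (default 40 x 40 at 500 m).
#' @param seed Integer master seed for the city.
#' @param uhi_amplitude UHI offset in degrees C at 100% imperviousness.
#' @param uhi_seasonal_modulation Seasonal swing of the UHI in `[0, 1]`
#'   (0 = constant; 1 = doubles at the summer peak, vanishes in winter).
#' @param annual_mean_c,seasonal_amplitude_c Background climate sinusoid.
#' @param weather_ar1 Day-to-day autocorrelation of the weather anomaly,
#'   in `[0, 1)`.
#' @param weather_sd_c Stationary s.d. of the weather anomaly, degrees C
#'   (innovations are truncated at 8 s.d., bounding all temperatures).
#' @param uhi_shape `"linear"` (offset proportional to imperviousness),
#'   `"binary"` (core cells at 100%, others 0 - uniform urban offset), or
#'   `"plateau"` (linear up to 80% imperviousness, flat above).
#' @param imperv_core_radius,imperv_decay Imperviousness profile: 100% inside
#'   the core radius, exponential decay with the given scale outside (cells).
#' @param water_fraction Fraction of cells flooded as a contiguous water body.
#' @param hill_height_m,hill_radius Height and Gaussian radius of an optional
#'   hill in one grid corner (0 = flat terrain at 100 m).
#' @param total_adults Total adult population of the domain.
#' @param pop_impervious_spearman Target Spearman rank correlation between
#'   population and imperviousness over land cells (default 0.47).
#' @param pop_concentration Log-scale s.d. of the population field (how
#'   concentrated inhabitants are in dense cells).
#' @param age_shares Named adult age-group shares (sum to 1).
#' @param baseline_mortality Named annual deaths per 100k per age group.
#' @param life_expectancy Named remaining life years per age group.
#' @param erf_params Data frame with columns `age_group`, `mmt_c`,
#'   `log_rr_cold`, `log_rr_warm`, `curvature` (risk at the cold/warm end of
#'   the observed range; power-law approach to the MMT).
#' @param n_draws,coefficient_sd ERF uncertainty ensemble: number of Monte
#'   Carlo draws and the Gaussian s.d. applied independently to (MMT, cold
#'   log RR, warm log RR).
#' @param start_date,end_date Analysis window (default 2015-2017).
#' @param erf_interpolation Interpolation rule for the generated curves.
#' @return A `city_recipe` object.
#' @export
city_recipe <- function(n_rows = 40, n_cols = 40, cell_size = 500, seed = 1L,
                        uhi_amplitude = 2, uhi_seasonal_modulation = 0.3,
                        annual_mean_c = 12, seasonal_amplitude_c = 8,
                        weather_ar1 = 0.7, weather_sd_c = 3,
                        uhi_shape = c("linear", "binary", "plateau"),
                        imperv_core_radius = NULL, imperv_decay = NULL,
                        water_fraction = 0.05,
                        hill_height_m = 0, hill_radius = 4,
                        total_adults = 5e5,
                        pop_impervious_spearman = 0.47,
                        pop_concentration = 1,
                        age_shares = default_age_shares(),
                        baseline_mortality = default_baseline_mortality(),
                        life_expectancy = default_life_expectancy(),
                        erf_params = default_erf_params(),
                        n_draws = 100, coefficient_sd = 0.05,
                        start_date = as.Date("2015-01-01"),
                        end_date = as.Date("2017-12-31"),
                        erf_interpolation = "monotone_cubic") {
  uhi_shape <- match.arg(uhi_shape)
  if (uhi_amplitude < 0) stop("uhi_amplitude must be >= 0")
  if (uhi_seasonal_modulation < 0 || uhi_seasonal_modulation > 1) {
    stop("uhi_seasonal_modulation must lie in [0, 1]")
  }
  if (weather_ar1 < 0 || weather_ar1 >= 1) {
    stop("weather_ar1 must lie in [0, 1)")
  }
  if (weather_sd_c < 0) stop("weather_sd_c must be >= 0")
  if (water_fraction < 0 || water_fraction >= 0.5) {
    stop("water_fraction must lie in [0, 0.5)")
  }
  if (n_draws < 1) stop("n_draws must be >= 1")
  if (coefficient_sd < 0) stop("coefficient_sd must be >= 0")
  if (abs(sum(age_shares) - 1) > 1e-9) stop("age_shares must sum to 1")
  if (!setequal(names(age_shares), AGE_GROUPS)) {
    stop("age_shares must be named by the five adult age groups")
  }
  if (any(baseline_mortality < 0)) stop("baseline mortality must be >= 0")
  if (!setequal(erf_params$age_group, AGE_GROUPS)) {
    stop("erf_params must cover the five adult age groups")
  }
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (end_date <= start_date) stop("end_date must be after start_date")
  # profile scales with the domain so small test grids keep a rural ring
  # (0.15 / 0.2 of the short side: 6 and 8 cells on the default 40 x 40)
  if (is.null(imperv_core_radius)) {
    imperv_core_radius <- max(2, round(0.15 * min(n_rows, n_cols)))
  }
  if (is.null(imperv_decay)) {
    imperv_decay <- max(2, 0.2 * min(n_rows, n_cols))
  }
  structure(as.list(environment()), class = "city_recipe")
}

# --- generator -------------------------------------------------------------

imperviousness_field <- function(recipe, spec) {
  k <- seq_len(n_cells(spec))
  r0 <- (spec$n_rows + 1) / 2
  c0 <- (spec$n_cols + 1) / 2
  d <- sqrt((cell_row(spec, k) - r0)^2 + (cell_col(spec, k) - c0)^2)
  if (recipe$uhi_shape == "binary") {
    ifelse(d <= recipe$imperv_core_radius, 100, 0)
  } else {
    100 * exp(-pmax(0, d - recipe$imperv_core_radius) / recipe$imperv_decay)
  }
}

# effective UHI weight per cell given the shape option
uhi_weight <- function(imperv, shape) {
  f <- imperv / 100
  switch(shape,
    linear = f,
    binary = f,               # imperviousness is already 0/100
    plateau = pmin(f, 0.8) / 0.8)
}

seasonal_background <- function(dates, mean_c, amplitude_c) {
  doy <- as.integer(format(dates, "%j"))
  # coldest mid-January, warmest mid-July (northern-hemisphere city)
  mean_c - amplitude_c * cos(2 * pi * (doy - 15) / 365.25)
}

uhi_modulation <- function(dates, s) {
  doy <- as.integer(format(dates, "%j"))
  # UHI peaks in summer (around day 196) when s > 0
  1 + s * cos(2 * pi * (doy - 196) / 365.25)
}

ar1_series <- function(n, rho, sd) {
  if (sd == 0) return(numeric(n))
  innov_sd <- sd * sqrt(1 - rho^2)
  z <- pmin(pmax(stats::rnorm(n), -8), 8)
  e <- numeric(n)
  e[1] <- z[1] * sd
  for (i in seq_len(n)[-1]) e[i] <- rho * e[i - 1] + z[i] * innov_sd
  pmin(pmax(e, -8 * sd), 8 * sd)
}

#' Generate a synthetic city
#'
#' Deterministically (for a fixed recipe seed) generates the static layers,
#' daily temperature cube, demography/mortality tables and age-group ERF
#' ensembles of a synthetic city. Imperviousness decays from a central core;
#' population is rank-correlated with imperviousness at the recipe's target
#' Spearman correlation; a contiguous water body and a corner hill are present
#' iff requested; the temperature field follows the AR(1)-plus-seasonal model
#' described in the package vignette with a UHI offset tied to imperviousness.
#'
#' @param recipe A [city_recipe()].
#' @return A `synthetic_city`: list with `spec`, `layers` (imperviousness,
#'   elevation, population, land_class), `cube`, `erfs` (per-age
#'   [erf_ensemble()]), `demography`, `baseline`, `life_table`,
#'   `reference_series`, and `truth` (the recipe).
#' @export
generate_city <- function(recipe) {
  stopifnot(inherits(recipe, "city_recipe"))
  spec <- grid_spec(recipe$n_rows, recipe$n_cols, recipe$cell_size)
  nc <- n_cells(spec)
  k <- seq_len(nc)

  imperv <- imperviousness_field(recipe, spec)

  # water: contiguous body nearest a seeded corner
  water <- logical(nc)
  n_water <- round(recipe$water_fraction * nc)
  if (n_water > 0) {
    water <- with_stream(mix_seed(recipe$seed, "water"), {
      corner <- sample(4L, 1L)
      cr <- c(1, 1, spec$n_rows, spec$n_rows)[corner]
      cc <- c(1, spec$n_cols, 1, spec$n_cols)[corner]
      d <- sqrt((cell_row(spec, k) - cr)^2 + (cell_col(spec, k) - cc)^2)
      k %in% order(d, k)[seq_len(n_water)]
    })
    imperv[water] <- 0
  }

  # elevation: flat 100 m base plus optional Gaussian hill in the corner
  # opposite the urban core
  elev <- rep(100, nc)
  if (recipe$hill_height_m > 0) {
    d <- sqrt((cell_row(spec, k) - 1)^2 + (cell_col(spec, k) - 1)^2)
    elev <- elev + recipe$hill_height_m * exp(-d^2 / (2 * recipe$hill_radius^2))
  }

  # land class: urban where at least half-sealed, water as placed
  land_class <- ifelse(water, "water", ifelse(imperv >= 50, "urban", "rural"))
  if (!any(land_class == "urban") || !any(land_class == "rural")) {
    stop("degenerate grid: need both urban and rural cells")
  }

  # population: Gaussian-copula coupling to imperviousness ranks at the
  # target Spearman correlation, log-normal concentration
  pop <- numeric(nc)
  land <- !water
  pop[land] <- with_stream(mix_seed(recipe$seed, "population"), {
    n <- sum(land)
    u <- (rank(imperv[land], ties.method = "average") - 0.5) / n
    zi <- stats::qnorm(u)
    a <- 2 * sin(pi * recipe$pop_impervious_spearman / 6)
    g <- a * zi + sqrt(1 - a^2) * stats::rnorm(n)
    w <- exp(recipe$pop_concentration * g)
    recipe$total_adults * w / sum(w)
  })

  layers <- list(
    imperviousness = static_layer(spec, "imperviousness_pct", imperv),
    elevation = static_layer(spec, "elevation_m", elev),
    population = static_layer(spec, "population_count", pop),
    land_class = static_layer(spec, "land_class", land_class))

  # temperature cube: background + UHI + shared AR(1) anomaly
  dates <- seq(recipe$start_date, recipe$end_date, by = "day")
  tbg <- seasonal_background(dates, recipe$annual_mean_c,
                             recipe$seasonal_amplitude_c)
  m <- uhi_modulation(dates, recipe$uhi_seasonal_modulation)
  eps <- with_stream(mix_seed(recipe$seed, "weather"),
                     ar1_series(length(dates), recipe$weather_ar1,
                                recipe$weather_sd_c))
  offset <- recipe$uhi_amplitude * uhi_weight(imperv, recipe$uhi_shape)
  vals <- (tbg + eps) + outer(m, offset)   # days x cells
  cube <- temperature_cube(spec, dates, vals)

  # reference series for ERF calibration: population-weighted land mean
  wl <- pop[land]
  ref <- as.vector(cube$values[, land, drop = FALSE] %*% wl) / sum(wl)

  erfs <- generate_erf_ensemble(recipe$erf_params, ref, recipe$n_draws,
                                recipe$coefficient_sd,
                                seed = mix_seed(recipe$seed, "erf"),
                                interpolation = recipe$erf_interpolation)

  demography <- data.frame(
    age_group = AGE_GROUPS,
    share = unname(recipe$age_shares[AGE_GROUPS]),
    population = unname(recipe$age_shares[AGE_GROUPS]) * recipe$total_adults)
  baseline <- data.frame(
    age_group = AGE_GROUPS,
    annual_deaths_per_100k = unname(recipe$baseline_mortality[AGE_GROUPS]))
  life_table <- data.frame(
    age_group = AGE_GROUPS,
    life_expectancy_years = unname(recipe$life_expectancy[AGE_GROUPS]))

  structure(list(spec = spec, layers = layers, cube = cube, erfs = erfs,
                 demography = demography, baseline = baseline,
                 life_table = life_table, reference_series = ref,
                 dates = dates, truth = recipe),
            class = "synthetic_city")
}

#' @export
print.synthetic_city <- function(x, ...) {
  cat(sprintf("<synthetic_city> %d x %d cells, %d days, %d ERF draws\n",
              x$spec$n_rows, x$spec$n_cols, length(x$dates),
              length(x$erfs[[1]]$draws)))
  invisible(x)
}

# true U-shaped log-RR in percentile space for one age group:
# power-law limbs meeting at the MMT, anchored at the observed extremes
true_log_rr <- function(t, mmt, log_rr_cold, log_rr_warm, curvature,
                        t_lo, t_hi) {
  out <- numeric(length(t))
  cold <- t < mmt
  if (mmt > t_lo) {
    out[cold] <- log_rr_cold * ((mmt - t[cold]) / (mmt - t_lo))^curvature
  }
  if (t_hi > mmt) {
    out[!cold] <- log_rr_warm * ((t[!cold] - mmt) / (t_hi - mmt))^curvature
  }
  out
}

#' Generate an ERF uncertainty ensemble
#'
#' Builds, per age group, a central exposure-response curve from the recipe's
#' shape parameters (U-shaped log RR with known MMT and end-point risks over
#' the reference-series range) plus `n_draws` Monte-Carlo perturbations. Draw
#' curves perturb (MMT, cold log RR, warm log RR) with independent Gaussian
#' noise of s.d. `coefficient_sd`; every draw is recentred so RR at its own
#' MMT is 1. With `coefficient_sd = 0` all draws equal the central curve.
#'
#' @param erf_params Data frame as in [city_recipe()].
#' @param reference_series Daily city-mean temperatures.
#' @param n_draws Number of Monte-Carlo draws (>= 1).
#' @param coefficient_sd Gaussian perturbation s.d.
#' @param seed Integer seed.
#' @param interpolation Interpolation rule for the curves.
#' @param percentiles Percentile grid at which curves are tabulated.
#' @return Named list of [erf_ensemble()] objects, one per age group.
#' @export
generate_erf_ensemble <- function(erf_params, reference_series, n_draws,
                                  coefficient_sd, seed,
                                  interpolation = "monotone_cubic",
                                  percentiles = c(0, 1, 2.5, 5,
                                                  seq(10, 90, by = 10),
                                                  95, 97.5, 99, 100)) {
  if (n_draws < 1) stop("n_draws must be >= 1")
  if (coefficient_sd < 0) stop("coefficient_sd must be >= 0")
  x <- as.numeric(reference_series)
  t_lo <- min(x)
  t_hi <- max(x)
  knots <- stats::quantile(x, percentiles / 100, type = 7, names = FALSE)
  obs <- range(x)

  build <- function(age, mmt, lc, lw, curv) {
    mmt <- min(max(mmt, t_lo + 0.5), t_hi - 0.5)  # keep MMT inside the range
    kt <- sort(unique(c(knots, mmt)))
    lrr <- true_log_rr(kt, mmt, lc, lw, curv, t_lo, t_hi)
    erf_curve(kt, lrr, obs, age, interpolation = interpolation)
  }

  out <- list()
  for (i in seq_len(nrow(erf_params))) {
    p <- erf_params[i, ]
    central <- build(p$age_group, p$mmt_c, p$log_rr_cold, p$log_rr_warm,
                     p$curvature)
    draws <- with_stream(mix_seed(seed, "draws", i), {
      lapply(seq_len(n_draws), function(j) {
        pert <- stats::rnorm(3, sd = coefficient_sd)
        build(p$age_group, p$mmt_c + pert[1], p$log_rr_cold + pert[2],
              p$log_rr_warm + pert[3], p$curvature)
      })
    })
    out[[p$age_group]] <- erf_ensemble(central, draws)
  }
  out[AGE_GROUPS]
}

#' City archetype for cohort generation
#'
#' A partial recipe (climate and UHI settings) plus a Koppen-Geiger label,
#' used to stamp out cohort cities.
#'
#' @param koppen Koppen-Geiger class label (e.g. `"Cfb"`).
#' @param ... Overrides passed to [city_recipe()] (e.g. `annual_mean_c`).
#' @return A `city_archetype`.
#' @export
city_archetype <- function(koppen, ...) {
  structure(list(koppen = koppen, overrides = list(...)),
            class = "city_archetype")
}

#' Generate a multi-city synthetic cohort
#'
#' Cities cycle through the archetype list; each city's seed is derived
#' deterministically from the master seed and the city index, so a fixed
#' master seed reproduces the cohort bit-identically.
#'
#' @param n_cities Number of cities (>= 1).
#' @param archetypes Non-empty list of [city_archetype()] objects.
#' @param master_seed Integer master seed.
#' @param ... Further [city_recipe()] overrides applied to every city.
#' @return List of `synthetic_city` objects, each with `$city_id` and
#'   `$koppen` set.
#' @export
generate_multicity_cohort <- function(n_cities, archetypes, master_seed, ...) {
  if (n_cities < 1) stop("n_cities must be >= 1")
  if (length(archetypes) == 0L) stop("archetype list must be non-empty")
  common <- list(...)
  lapply(seq_len(n_cities), function(i) {
    arch <- archetypes[[(i - 1L) %% length(archetypes) + 1L]]
    args <- utils::modifyList(
      c(list(seed = mix_seed(master_seed, "city", i)), common),
      arch$overrides)
    city <- generate_city(do.call(city_recipe, args))
    city$city_id <- sprintf("city_%02d", i)
    city$koppen <- arch$koppen
    city
  })
}
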