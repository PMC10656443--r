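# Config-driven orchestration: validated run configuration, the end-to-end
# pipeline (simulate -> mask -> calibrate -> attribute -> differentials ->
# aggregate -> economics -> report), CSV outputs and a machine-readable run
# manifest. Identical configurations produce identical outputs.

#' Default run configuration
#'
#' Nested list of every tunable with its default: the cohort (number of
#' cities, archetype climates, recipe overrides), the analysis settings
#' (elevation threshold 100 m, extreme-day fraction 0.02, imperviousness bin
#' width 5, histogram bin 0.02 degC, cell-level warm/cold classification,
#' 95% level for impact-median intervals and 90% for the adverse-city count)
#' and the economic parameters ([default_economics()]).
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    out_dir = "uhimort-run",
    cohort = list(
      n_cities = 4L,
      archetypes = list(
        list(koppen = "Cfb", annual_mean_c = 11, seasonal_amplitude_c = 7,
             uhi_amplitude = 2),
        list(koppen = "Csa", annual_mean_c = 17, seasonal_amplitude_c = 9,
             uhi_amplitude = 2.5),
        list(koppen = "Dfb", annual_mean_c = 8, seasonal_amplitude_c = 11,
             uhi_amplitude = 1.8),
        list(koppen = "BSk", annual_mean_c = 15, seasonal_amplitude_c = 10,
             uhi_amplitude = 2.2)),
      recipe = list()),
    analysis = list(
      elevation_threshold_m = 100,
      extreme_fraction = 0.02,
      imperv_bin_width = 5,
      histogram_bin_c = 0.02,
      classification = "cell",
      ci_level_median = 0.95,
      ci_level_count = 0.90),
    economics = default_economics())
}

check_known_keys <- function(x, ref, path = "config") {
  unknown <- setdiff(names(x), names(ref))
  if (length(unknown)) {
    stop(path, ": unknown key(s): ", paste(unknown, collapse = ", "))
  }
  for (k in names(x)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]])) && is.list(x[[k]])) {
      check_known_keys(x[[k]], ref[[k]], paste(path, k, sep = "$"))
    }
  }
}

#' Validate a run configuration
#'
#' Accepts a nested list or a YAML file path; unknown keys are rejected
#' (typo safety), defaults are filled in, and ranges are checked before any
#' computation.
#'
#' @param config Nested list, or path to a YAML config file.
#' @return Validated `run_config` list.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  ref <- default_config()
  # archetypes and recipe are free-form (validated by city_recipe)
  check_ref <- ref
  check_ref$cohort$archetypes <- NULL
  check_ref$cohort$recipe <- NULL
  cfg_check <- config
  if (!is.null(cfg_check$cohort)) {
    cfg_check$cohort$archetypes <- NULL
    cfg_check$cohort$recipe <- NULL
  }
  check_known_keys(cfg_check, check_ref)
  cfg <- utils::modifyList(ref, config)
  a <- cfg$analysis
  if (a$extreme_fraction <= 0 || a$extreme_fraction > 0.5) {
    stop("analysis$extreme_fraction must lie in (0, 0.5]")
  }
  if (a$elevation_threshold_m < 0) {
    stop("analysis$elevation_threshold_m must be >= 0")
  }
  if (a$imperv_bin_width <= 0) stop("analysis$imperv_bin_width must be > 0")
  if (a$histogram_bin_c <= 0) stop("analysis$histogram_bin_c must be > 0")
  if (!a$classification %in% c("cell", "domain")) {
    stop("analysis$classification must be 'cell' or 'domain'")
  }
  for (lv in c("ci_level_median", "ci_level_count")) {
    if (a[[lv]] <= 0 || a[[lv]] >= 1) stop("analysis$", lv, " outside (0, 1)")
  }
  if (cfg$cohort$n_cities < 1) stop("cohort$n_cities must be >= 1")
  if (length(cfg$cohort$archetypes) == 0L) {
    stop("cohort$archetypes must be non-empty")
  }
  if (!is.null(cfg$cohort$recipe$uhi_amplitude) &&
      cfg$cohort$recipe$uhi_amplitude < 0) {
    stop("cohort$recipe$uhi_amplitude must be >= 0")
  }
  structure(cfg, class = c("run_config", "list"))
}

# polynomial rolling hash over the serialized config: a stable fingerprint
# for the manifest (not cryptographic)
config_hash <- function(config) {
  bytes <- as.integer(serialize(unclass(config), NULL, ascii = TRUE))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Analyse one city end to end
#'
#' Runs mask construction, extreme-day selection, central attribution,
#' differentials, period aggregation, per-draw impacts and economic
#' valuation for a single (synthetic or loaded) city.
#'
#' @param city A `synthetic_city`-shaped list.
#' @param analysis Analysis settings (see [default_config()]).
#' @param valuations A [calibrate_valuations()] result.
#' @return List: `mask`, `extremes`, `attribution`, `series`, `summary`,
#'   `per_age`, `economics`, `draws` (per-draw matrix), `metrics`.
#' @export
analyse_city <- function(city, analysis = default_config()$analysis,
                         valuations = calibrate_valuations()) {
  mask <- build_analysis_mask(city$layers$land_class, city$layers$elevation,
                              city$layers$population,
                              threshold = analysis$elevation_threshold_m)
  extremes <- find_extreme_days(city$cube, city$layers$population, mask,
                                fraction = analysis$extreme_fraction)
  baseline <- stats::setNames(city$baseline$annual_deaths_per_100k,
                              city$baseline$age_group)
  shares <- stats::setNames(city$demography$share, city$demography$age_group)
  attribution <- attribute_city(city$cube, mask, city$erfs, baseline, shares,
                                extremes = extremes,
                                classification = analysis$classification)
  series <- daily_differential(attribution)
  summary <- aggregate_periods(series, extremes)
  per_age <- annual_differential_by_age(series)
  econ <- economic_impact(summary, per_age, city$life_table, shares,
                          valuations)
  draws <- impact_by_draw(city, mask, extremes,
                          bin_width = analysis$histogram_bin_c)
  metrics <- city_metrics(city, mask, attribution, extremes)
  list(mask = mask, extremes = extremes, attribution = attribution,
       series = series, summary = summary, per_age = per_age,
       economics = econ, draws = draws, metrics = metrics)
}

#' Run the full pipeline from a configuration
#'
#' Stages: simulate the cohort, then per city mask / calibrate / attribute /
#' difference / aggregate / value, then cohort-level Monte-Carlo confidence
#' intervals and metric correlations. Writes `city_impacts.csv` (per-city
#' impact and valuation summaries), `cohort_summary.csv` (cohort medians and
#' intervals), `correlations.csv`, and `manifest.json` (config hash, seed,
#' package version) under `config$out_dir`.
#'
#' @param config A [validate_config()] input (list or YAML path).
#' @param quiet Suppress per-stage progress messages.
#' @return Invisibly, a list with the per-city results, cohort tables and
#'   manifest.
#' @export
run_pipeline <- function(config = list(), quiet = FALSE) {
  cfg <- validate_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  say("stage simulate: %d cities", cfg$cohort$n_cities)
  archetypes <- lapply(cfg$cohort$archetypes, function(a) {
    do.call(city_archetype, a)
  })
  cohort <- do.call(generate_multicity_cohort,
                    c(list(n_cities = cfg$cohort$n_cities,
                           archetypes = archetypes,
                           master_seed = cfg$seed),
                      cfg$cohort$recipe))

  valuations <- calibrate_valuations(cfg$economics)
  results <- list()
  for (city in cohort) {
    say("stage analyse: %s (%s)", city$city_id, city$koppen)
    res <- tryCatch(
      analyse_city(city, cfg$analysis, valuations),
      error = function(e) {
        stop("stage analyse failed for ", city$city_id, ": ",
             conditionMessage(e), call. = FALSE)
      })
    results[[city$city_id]] <- res
  }

  say("stage aggregate: cohort summaries")
  city_ids <- names(results)
  impacts <- do.call(rbind, lapply(city_ids, function(id) {
    cbind(city_id = id,
          koppen = cohort[[match(id, city_ids)]]$koppen,
          results[[id]]$summary, results[[id]]$economics)
  }))

  draw_mat <- sapply(results, function(r) r$draws[-1, "annual_net"])
  central <- sapply(results, function(r) r$draws["central", "annual_net"])
  mc_median <- mc_confidence(draw_mat, central,
                             level = cfg$analysis$ci_level_median, "median")
  mc_adverse <- mc_confidence(draw_mat, central,
                              level = cfg$analysis$ci_level_count,
                              "adverse_count")
  groups <- assign_climate_groups(
    stats::setNames(vapply(cohort, `[[`, "", "koppen"), city_ids))
  cohort_summary <- data.frame(
    quantity = c("annual_net_median", "adverse_city_count", "n_cities"),
    central = c(mc_median$central, mc_adverse$central, length(city_ids)),
    lower = c(mc_median$lower, mc_adverse$lower, NA),
    upper = c(mc_median$upper, mc_adverse$upper, NA),
    level = c(cfg$analysis$ci_level_median, cfg$analysis$ci_level_count, NA))

  metrics <- do.call(rbind, lapply(results, `[[`, "metrics"))
  impact_cols <- impacts[, c("annual_net", "heat_ext_mean", "cold_ext_mean",
                             "season_DJF", "season_JJA")]
  correlations <- if (length(city_ids) >= 5) {
    correlation_matrix(metrics, impact_cols)
  } else NULL

  say("stage report: writing outputs to %s", cfg$out_dir)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(impacts, file.path(cfg$out_dir, "city_impacts.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort_summary,
                   file.path(cfg$out_dir, "cohort_summary.csv"),
                   row.names = FALSE)
  if (!is.null(correlations)) {
    utils::write.csv(correlations,
                     file.path(cfg$out_dir, "correlations.csv"),
                     row.names = FALSE)
  }
  manifest <- list(
    package = "uhimort",
    version = as.character(utils::packageVersion("uhimort")),
    config_hash = config_hash(cfg),
    seed = cfg$seed,
    n_cities = length(city_ids),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(config = cfg, cohort = cohort, results = results,
                 impacts = impacts, cohort_summary = cohort_summary,
                 correlations = correlations, groups = groups,
                 mc = list(median = mc_median, adverse = mc_adverse),
                 manifest = manifest))
}
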