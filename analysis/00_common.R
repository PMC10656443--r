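# Shared setup for the analysis drivers: the demo cohort (10 synthetic
# cities at the default study conditions, 2015-2017, 100 ERF draws) and its
# per-city analyses, cached under scratch/ so later drivers reuse them.

library(uhimort)

COHORT_SEED <- 2024L
N_CITIES <- 10L

demo_cohort <- function() {
  cache <- file.path("scratch", sprintf("cohort_%d.rds", COHORT_SEED))
  if (file.exists(cache)) return(readRDS(cache))
  message("generating ", N_CITIES, " synthetic cities (seed ", COHORT_SEED, ")")
  archetypes <- lapply(default_config()$cohort$archetypes,
                       function(a) do.call(city_archetype, a))
  cohort <- generate_multicity_cohort(N_CITIES, archetypes, COHORT_SEED)
  dir.create("scratch", showWarnings = FALSE)
  saveRDS(cohort, cache)
  cohort
}

demo_analyses <- function(cohort = demo_cohort()) {
  cache <- file.path("scratch", sprintf("analyses_%d.rds", COHORT_SEED))
  if (file.exists(cache)) return(readRDS(cache))
  message("analysing ", length(cohort), " cities")
  out <- lapply(cohort, analyse_city)
  names(out) <- vapply(cohort, `[[`, "", "city_id")
  saveRDS(out, cache)
  out
}

results_dir <- function(sub) {
  d <- file.path("results", sub)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}
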