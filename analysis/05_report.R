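#!/usr/bin/env Rscript
# Collate the headline numbers of the demo-cohort analysis into one table.
#
# Writes: results/report/headline.csv (and prints it).

source(file.path("analysis", "00_common.R"))

out <- results_dir("report")
summaries <- read.csv("results/attribution/city_summaries.csv")
mc <- read.csv("results/impact/mc_summary.csv")
vals <- read.csv("results/economics/city_valuations.csv")
builtup <- read.csv("results/impact/builtup_exposure.csv")

headline <- data.frame(
  quantity = c(
    "annual net differential, cohort median (deaths/100k/yr)",
    "heat-extreme-day differential, median (deaths/100k/day)",
    "heat-extreme increase vs rural, median (%)",
    "cold-extreme-day differential, median (deaths/100k/day)",
    "cold-extreme change vs rural, median (%)",
    "cities with adverse annual net impact (of 10)",
    "VSL heat valuation, median (EUR/adult/yr)",
    "VSL cold valuation, median (EUR/adult/yr)",
    "built-up (>=90% vs <=10%) heat-day differential, median (%)",
    "heat-day exposure bias from population weighting, median (%)"),
  value = c(
    round(median(summaries$annual_net), 2),
    round(median(summaries$heat_ext_mean), 3),
    round(median(summaries$heat_ext_pct_vs_rural), 1),
    round(median(summaries$cold_ext_mean), 3),
    round(median(summaries$cold_ext_pct_vs_rural), 1),
    mc$central[mc$quantity == "adverse_city_count"],
    round(median(vals$vsl_heat)),
    round(median(vals$vsl_cold)),
    round(median(builtup$pct, na.rm = TRUE), 1),
    round(median(builtup$exposure_bias_heat_pct), 2)))
write.csv(headline, file.path(out, "headline.csv"), row.names = FALSE)

message("demo-cohort headline results:")
for (i in seq_len(nrow(headline))) {
  message(sprintf("  %-60s %s", headline$quantity[i], headline$value[i]))
}
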