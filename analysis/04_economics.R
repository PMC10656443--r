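#!/usr/bin/env Rscript
# Monetary valuation of the UHI mortality differentials: VSL-based heat,
# cold and net impacts per adult inhabitant per year, and the YLL/VOLY
# alternative with central and bounding VOLY estimates.
#
# Writes: results/economics/valuation_constants.csv and city_valuations.csv.

source(file.path("analysis", "00_common.R"))

analyses <- demo_analyses()
out <- results_dir("economics")

val <- calibrate_valuations()
constants <- data.frame(
  quantity = c("vsl_2021_eur", "voly_central_2021_eur", "voly_low_2021_eur",
               "voly_high_2021_eur", "vsl_per_voly_central",
               "vsl_per_voly_upper"),
  value = c(report_currency(val$vsl, 3), report_currency(val$voly, 2),
            round(report_currency(val$vsl, 3) /
                    report_currency(val$voly[["central"]], 2)),
            round(report_currency(val$vsl, 3) / val$voly[["high"]])))
write.csv(constants, file.path(out, "valuation_constants.csv"),
          row.names = FALSE)

city_val <- do.call(rbind, lapply(names(analyses), function(id) {
  cbind(city_id = id, analyses[[id]]$economics)
}))
write.csv(city_val, file.path(out, "city_valuations.csv"), row.names = FALSE)

# the VOLY/VSL share is computed on the heat and cold components (the net is
# a small difference of large terms and its ratio is unstable)
voly_share <- median(c(
  median(city_val$voly_heat_central) / median(city_val$vsl_heat),
  median(city_val$voly_cold_central) / median(city_val$vsl_cold)))
message("VSL = ", report_currency(val$vsl, 3) / 1e6,
        " million 2021-EUR; VOLY = ", report_currency(val$voly[["central"]], 2),
        " 2021-EUR (", constants$value[5], " VOLY per VSL)")
message("median heat/cold valuation across ", nrow(city_val), " cities: ",
        round(median(city_val$vsl_heat)), " / ",
        round(median(city_val$vsl_cold)), " EUR per adult per year")
message("VOLY-based valuation is ~", round(100 * voly_share),
        "% of the VSL-based one at the central VOLY")
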