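# Monetary valuation of attributable-mortality differentials: value of
# statistical life (VSL) with PPP/CPI conversion to target-year euros, and
# years of life lost (YLL) valued per life year (VOLY). Unrounded values are
# carried internally; reporting rounds VSL-scale amounts to 3 significant
# figures and VOLY-scale amounts to 2, matching conventional print precision.

#' Currency conversion basis
#'
#' @param ppp Purchasing power parity, EUR per USD, for the base year
#'   (1 for EUR-denominated inputs).
#' @param cpi_base,cpi_target Consumer price index for the base and target
#'   years (19-country Euro area).
#' @return A `currency_basis`.
#' @export
currency_basis <- function(ppp, cpi_base, cpi_target) {
  if (any(c(ppp, cpi_base, cpi_target) <= 0)) {
    stop("PPP and CPI values must be positive")
  }
  structure(list(ppp = ppp, cpi_base = cpi_base, cpi_target = cpi_target),
            class = "currency_basis")
}

#' Convert a valuation to target-year euros
#'
#' `amount x PPP x CPI_target / CPI_base`: PPP converts the base-year
#' currency to euros, the CPI ratio accounts for inflation to the target
#' year. The conversion is multiplicative-composable along a consistent CPI
#' chain.
#'
#' @param amount Amount in base-year currency (positive).
#' @param basis A [currency_basis()].
#' @return Amount in target-year EUR (unrounded).
#' @export
convert_valuation <- function(amount, basis) {
  stopifnot(inherits(basis, "currency_basis"))
  if (any(amount <= 0)) stop("amount must be positive")
  amount * basis$ppp * basis$cpi_target / basis$cpi_base
}

#' Round a currency amount for reporting
#'
#' @param x Amount(s).
#' @param sig Significant figures (3 for VSL-scale, 2 for VOLY-scale).
#' @return Rounded amount(s).
#' @export
report_currency <- function(x, sig = 3) signif(x, sig)

#' VSL valuation of a mortality differential
#'
#' `(annual differential per 100k / 100,000) x VSL`, in EUR per adult
#' inhabitant per year; applied separately to heat, cold and net components
#' (valuation is linear in the differential).
#'
#' @param annual_diff_per_100k Annual attributable-mortality differential(s),
#'   deaths per 100k per year (may be a named vector of components).
#' @param vsl Value of statistical life in target-year EUR.
#' @return EUR per adult per year, same shape as the input.
#' @export
vsl_impact <- function(annual_diff_per_100k, vsl) {
  annual_diff_per_100k / 1e5 * vsl
}

#' Years of life lost from per-age mortality differentials
#'
#' `sum_a AN_a x LE_a`: each age group's annual attributable-death
#' differential weighted by the remaining life expectancy of that group.
#'
#' @param per_age_diff Named annual deaths per 100k per age group.
#' @param life_table Data frame `age_group`, `life_expectancy_years`, or a
#'   named numeric of remaining life years.
#' @return YLL per 100k per year.
#' @export
compute_yll <- function(per_age_diff, life_table) {
  le <- if (is.data.frame(life_table)) {
    stats::setNames(life_table$life_expectancy_years, life_table$age_group)
  } else life_table
  if (!all(names(per_age_diff) %in% names(le))) {
    stop("life table is missing age group(s): ",
         paste(setdiff(names(per_age_diff), names(le)), collapse = ", "))
  }
  if (any(le < 0)) stop("life expectancy must be non-negative")
  sum(per_age_diff * le[names(per_age_diff)])
}

#' VOLY valuation of years of life lost
#'
#' `(YLL per 100k / 100,000) x VOLY`, in EUR per adult inhabitant per year,
#' computed for central, low and high VOLY estimates.
#'
#' @param yll_per_100k YLL per 100k per year.
#' @param voly Value(s) of a life year in target-year EUR (scalar or named
#'   vector, e.g. `c(central = , low = , high = )`).
#' @return EUR per adult per year, one entry per VOLY value.
#' @export
voly_impact <- function(yll_per_100k, voly) {
  yll_per_100k / 1e5 * voly
}

#' Default economic parameters
#'
#' The valuation inputs used throughout: VSL of 3.6 million 2005-USD
#' converted with Euro-area PPP 0.853 EUR/USD (2005) and CPI 84.7 (2005) to
#' 107.8 (2021); VOLY of 40,000 2010-EUR converted with CPI 93.1 (2010), with
#' bounding estimates of 29,000-116,000 2021-EUR.
#'
#' @return Nested list of parameters.
#' @export
default_economics <- function() {
  list(vsl_usd_2005 = 3.6e6, ppp_2005 = 0.853,
       cpi_2005 = 84.7, cpi_2010 = 93.1, cpi_2021 = 107.8,
       voly_eur_2010 = 4e4,
       voly_low_eur_2021 = 2.9e4, voly_high_eur_2021 = 1.16e5)
}

#' Calibrated 2021-EUR valuation constants
#'
#' Applies [convert_valuation()] to the economic parameters, returning the
#' target-year VSL and the central/low/high VOLY.
#'
#' @param params Parameter list as from [default_economics()].
#' @return List `vsl`, `voly` (named central/low/high), both unrounded
#'   2021-EUR.
#' @export
calibrate_valuations <- function(params = default_economics()) {
  vsl <- convert_valuation(
    params$vsl_usd_2005,
    currency_basis(params$ppp_2005, params$cpi_2005, params$cpi_2021))
  voly_central <- convert_valuation(
    params$voly_eur_2010,
    currency_basis(1, params$cpi_2010, params$cpi_2021))
  list(vsl = vsl,
       voly = c(central = voly_central,
                low = params$voly_low_eur_2021,
                high = params$voly_high_eur_2021))
}

#' Economic impact of a city's UHI mortality differentials
#'
#' Values the annual heat/cold/net attributable-mortality differentials per
#' adult inhabitant per year under the VSL approach, and the per-age
#' differentials under YLL/VOLY accounting (central, low and high VOLY).
#' Per-age differentials are rates per 100k of each age group; they are
#' weighted by the adult age-structure shares to the per-100k-adults scale
#' before the life-expectancy multiplication, so YLL and VSL accounting share
#' one denominator.
#'
#' @param summary An [aggregate_periods()] row (all-adult components).
#' @param per_age Data frame from [annual_differential_by_age()].
#' @param life_table Data frame `age_group`, `life_expectancy_years`.
#' @param age_structure Named adult shares per age group (sum 1).
#' @param valuations A [calibrate_valuations()] result.
#' @return One-row data frame (`economic_impact`): `vsl_heat`, `vsl_cold`,
#'   `vsl_net` (EUR/adult/yr), YLL per 100k (net and heat/cold components),
#'   `voly_net_central` / `_low` / `_high`, and central-VOLY heat/cold
#'   valuations.
#' @export
economic_impact <- function(summary, per_age, life_table, age_structure,
                            valuations = calibrate_valuations()) {
  if (abs(sum(age_structure) - 1) > 1e-9) {
    stop("age_structure shares must sum to 1")
  }
  v <- vsl_impact(c(heat = summary$annual_heat, cold = summary$annual_cold,
                    net = summary$annual_net), valuations$vsl)
  yll_of <- function(col) {
    an_per_adult <- age_structure[per_age$age_group] * per_age[[col]]
    compute_yll(stats::setNames(an_per_adult, per_age$age_group), life_table)
  }
  yll <- yll_of("annual_net")
  yll_heat <- yll_of("annual_heat")
  yll_cold <- yll_of("annual_cold")
  voly <- voly_impact(yll, valuations$voly)
  out <- data.frame(vsl_heat = v[["heat"]], vsl_cold = v[["cold"]],
                    vsl_net = v[["net"]], yll_per_100k = yll,
                    yll_heat_per_100k = yll_heat,
                    yll_cold_per_100k = yll_cold,
                    voly_net_central = voly[["central"]],
                    voly_net_low = voly[["low"]],
                    voly_net_high = voly[["high"]],
                    voly_heat_central =
                      voly_impact(yll_heat, valuations$voly[["central"]]),
                    voly_cold_central =
                      voly_impact(yll_cold, valuations$voly[["central"]]))
  class(out) <- c("economic_impact", "data.frame")
  out
}
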