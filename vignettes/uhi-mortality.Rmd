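---
title: "Attributing temperature-related mortality to the urban heat island"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attributing temperature-related mortality to the urban heat island}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cities are warmer than their rural surroundings. This urban heat island
(UHI) raises mortality risk on hot days and lowers it on cold days, and
because most of the European year is on the cold side of the optimum,
the two effects can net out either way. `uhimort` quantifies this balance
on a gridded city domain: for every cell and day it attributes a fraction
of baseline mortality to non-optimal temperature, differences the urban
and rural averages, aggregates over periods (annual, meteorological
seasons, heat/cold extreme days), propagates exposure-response
uncertainty by Monte Carlo, and converts the mortality differentials to
money under value-of-statistical-life (VSL) and value-of-life-year
(VOLY) accounting.

## The attribution model

Risk is described by age-group exposure-response functions (ERFs):
lag-cumulative relative risk RR(T) against daily mean temperature, with
RR = 1 at the minimum mortality temperature (MMT). The curves arrive in
relative temperature percentiles (the output of an upstream two-stage
time-series regression, which this package does not re-fit) and are
translated to absolute temperature against the city's domain-mean daily
series: knot temperatures are the empirical quantiles of that series at
the curve's percentiles (`stats::quantile` type 7, the single supported
rule so results are bit-reproducible), the observed range is the series
min/max, and the curve is recentred so RR(MMT) = 1.

For a cell with daily mean temperature T, the attributable fraction is

AF = (RR(T) − 1) / RR(T),

and the daily attributable number per 100,000 inhabitants of an age
group is AF × M_a / d_y, where M_a is the group's annual all-cause
mortality per 100k and d_y the actual calendar-year length (366 in leap
years, rather than a fixed 365.25). Each
cell-day is classified warm or cold against the age-specific MMT
(strictly above = warm; a day at the MMT has AF = 0, so its label is
inert). Because the MMT falls with age, one temperature can be warm for
the old and cold for the young. Age groups are combined with the local
adult age-structure shares; a fixed standard structure (ESP2013, shipped
as a plain-text asset) is available for cross-city standardization.

The UHI impact is the difference between the *unweighted* urban-cell
mean and rural-cell mean of the attributable number, per day. Unweighted
means take the perspective of an individual inhabitant — where would the
same person face more risk — rather than the population total;
`exposure_bias()` quantifies how much population weighting would shift
the urban mean, given that population concentrates where imperviousness
(and hence UHI) is highest.

Cells containing water are excluded from both strata, as are cells whose
elevation differs by more than 100 m from the domain
population-weighted mean elevation (computed over all land cells before
any exclusion). Heat and cold extreme days are the warmest/coldest 2%
of days of the analysis window — 22 days for a three-year daily window —
ranked by the domain population-weighted mean series, with k rounded
half-up and ties resolved to the earlier date.

## Interpolation and numerical choices

* Log-RR is interpolated between knots with a monotone-shape-preserving
  cubic (`splinefun(method = "monoH.FC")`), which avoids the spurious
  risk dips a plain cubic can introduce. A `"linear"` mode exists for
  curves that are piecewise linear by construction (the closed-form
  test harness uses it). With two knots per limb the cubic reduces to
  the linear case.
* Beyond the observed temperature range the curve is clamped at its
  boundary value: risk is only quantified inside the range the curves
  were estimated on.
* The MMT is located by grid search at 0.1 °C resolution over the
  observed range (candidate set augmented with the knots, ties broken
  toward the warmer candidate — conservative, classifying fewer days as
  warm), then polished with `optimize()` so the curve is recentred
  against the continuous minimum. The Fritsch–Carlson cubic can
  undershoot the bottom knot by a few 10⁻⁴ between knots; recentring on
  the continuous minimum keeps RR ≥ 1 − 10⁻⁹ everywhere on a U-shaped
  curve. Interpolation can still leave RR marginally below 1 in corner
  cases: values above 1 − 10⁻⁶ are clamped to 1 (AF = 0), anything
  lower raises an error.
* Central (best-estimate) impacts are computed exactly, cell by cell
  and day by day. The 100–1000-draw uncertainty ensembles are
  evaluated through fine temperature histograms (0.02 °C bins) per
  stratum and period: AF is a function of temperature alone, so
  aggregating counts first reduces the per-draw cost from
  O(cells × days) to O(bins) at a relative error well below the
  ensemble spread (about 0.3% on the annual net differential of the
  demo city, against a Monte-Carlo CI several tens of percent wide).
* Confidence intervals are empirical quantiles across draw-level cohort
  summaries (median across cities; count of cities with adverse annual
  net impact). The adverse-count interval uses the 90% level; impact
  medians default to 95% with a config option, since only the count's
  level is unambiguous in the source material.
* Spearman correlations between city metrics and impacts use the exact
  permutation null for n ≤ 9 (no ties) and the large-sample
  approximation otherwise; entries with p ≥ 0.01 are masked.

## The synthetic-city generator

Real inputs of this analysis are large and partly proprietary (urban
climate model fields, register mortality, deposited curve sets), so the
package ships a generator with known ground truth:

T(cell, d) = T_bg(d) + A · (imperviousness/100) · m(d) + ε(d)

* T_bg: sinusoid with the recipe's annual mean and seasonal amplitude
  (coldest mid-January).
* A: UHI amplitude at 100% imperviousness (default 2 °C; linear in
  imperviousness by default so the closed-form oracle stays closed-form;
  a plateau option saturating at 80% exists but is off by default, and a
  binary option gives a uniform urban offset for the recovery harness).
* m(d): seasonal modulation of the UHI (default ±0.3, peaking in July).
* ε(d): AR(1) weather anomaly (default autocorrelation 0.7, stationary
  s.d. 3 °C), *shared across all cells*. Spatially uniform weather makes
  the imperviousness term the only urban–rural temperature difference,
  matching the interpretive frame of the analysis. Innovations are
  truncated at ±8 s.d., so temperatures are bounded by
  mean ± amplitude ± 8 s.d. + A(1 + m).

Imperviousness decays exponentially from a saturated core (core radius
and decay scale default to 0.15 and 0.2 of the short grid side — 6 and 8
cells on the default 40 × 40 grid — so smaller test grids keep a rural
ring). Land class is urban at ≥ 50% imperviousness; a contiguous water
body (default 5% of cells) and an optional > 100 m corner hill exercise
the exclusion rules. Population couples to imperviousness ranks through
a Gaussian copula calibrated to a target Spearman correlation (default
0.47, the empirically reported coupling), with log-normal concentration;
monotone transforms preserve the rank target exactly.

ERF ground truth per age group is a U on the log scale: power-law limbs
(default exponent 1.5) from the MMT to the observed extremes, with MMT
falling (19 → 17 °C) and end-point risks rising (RR 1.15/1.2 →
1.7/1.9) with age. Ensembles perturb (MMT, cold log RR, warm log RR)
with independent Gaussian noise (default s.d. 0.05); draw 0 is the
central curve and every draw is recentred to RR(MMT) = 1. Default
demography (shares 0.40/0.33/0.13/0.10/0.04), baseline mortality
(80–14,000 per 100k) and remaining life expectancy (50–4.5 years) are
round European-order values; they are study conditions, not tuning
knobs.

What the generator does *not* emulate: synoptic weather patterns and
spatially structured anomalies, intra-urban vulnerability
heterogeneity, nighttime-temperature effects, and harvesting
/displacement dynamics. Passing tests therefore validate the
*machinery* — attribution arithmetic, masking, aggregation, uncertainty
propagation, valuation — not the realism of any particular city's
numbers.

## Economic valuation

The VSL of 3.6 million 2005-USD is converted with the Euro-area
purchasing power parity (0.853 EUR/USD, 2005) and the CPI ratio
107.8/84.7 to 3.91 million 2021-EUR; the VOLY of 40,000 2010-EUR
converts with CPI 93.1 → 107.8 to 46,000 2021-EUR (bounds
29,000–116,000). VSL-scale amounts are reported at 3 significant
figures, VOLY-scale at 2; unrounded values are carried internally.
Mortality differentials per 100k translate to EUR per adult inhabitant
per year by dividing by 10⁵ and multiplying by the VSL. YLL accounting
weights each age group's differential — share-weighted to the
per-100k-adults scale so both accountings share one denominator — by
remaining life expectancy, valued per VOLY with no discounting of
future life years. The adult denominator is the population aged 20+,
the youngest modelled group.

## Design choices where the design was open

* **Cell-level vs domain-level warm/cold classification.** AF is
  computed per cell, so the default classifies each cell-day against
  the age-specific MMT using the cell's own temperature; a
  `classification = "domain"` switch labels whole days from the domain
  population-weighted series instead. On the demo cities the two differ
  only in shoulder seasons.
* **Seasons** are meteorological (DJF/MAM/JJA/SON), pooled across years
  by month, DJF spanning the year boundary. Annual nets are means over
  calendar years of yearly sums.
* **Elevation reference** uses the analysis-resolution population layer
  and all land cells, before exclusions.
* **Imperviousness gradient** bins cells at 5-percentage-point width of
  Δ imperviousness from the rural mean; cohort curves drop cities whose
  maximum Δ is below 80 points and suppress group medians supported by
  fewer than four cities.
* **Climate groups** follow first-letter base classes; singleton groups
  merge into the same-base group with the most second/third-letter
  agreement and take the base-class name.
* **Monte-Carlo coverage harness**: interval calibration is tested
  under a shared coefficient shift across cities (the analogue of
  pooled second-stage curve uncertainty), where the percentile interval
  is exactly nominal; with independent per-city noise the median's
  percentile interval over-covers, which is a property of the
  experiment, not of the machinery.

## Problem sizes

The test suite and the reproduction script use a 10-city demo cohort of
40 × 40 grids (500 m cells) over 2015–2017 with 100-draw ensembles —
about 8.8 million curve evaluations per city for the exact central
pass — and smaller grids (10–20 cells a side, 1 month–1 year) for
oracle comparisons; the closed-form recovery harness runs 20 seeds of a
16 × 16 binary-UHI city for one year. These sizes resolve every checked
effect well beyond its Monte-Carlo error.

## Limitations

City-level curves carry no urban–rural difference in vulnerability,
healthcare access or housing stock; the individual-inhabitant
perspective deliberately ignores where people actually live (that bias
is quantified separately, not folded in); the generator's UHI is linear
in imperviousness while empirical profiles flatten at high
imperviousness; valuations cover mortality only — morbidity,
productivity, energy and infrastructure costs are out of scope.
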