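# Temperature-mortality exposure-response functions (ERFs).
#
# Curves arrive in relative temperature percentiles (the second-stage output
# of the upstream two-stage epidemiological pipeline) and are translated to
# absolute temperature against a city's domain-mean reference series. Risk is
# interpolated on the log relative-risk scale; beyond the observed temperature
# range the curve is clamped at the boundary value, since risk is quantified
# only at the extremes of the observed range.

#' Percentile-space exposure-response curve
#'
#' @param percentiles Strictly ascending percentiles in `[0, 100]`.
#' @param log_rr Log relative risk at each percentile.
#' @param age_group One of `"20-44"`, `"45-64"`, `"65-74"`, `"75-84"`, `"85+"`.
#' @return A `percentile_curve` object.
#' @export
percentile_curve <- function(percentiles, log_rr, age_group) {
  age_group <- match.arg(age_group, AGE_GROUPS)
  percentiles <- as.numeric(percentiles)
  log_rr <- as.numeric(log_rr)
  if (length(percentiles) < 2L || length(percentiles) != length(log_rr)) {
    stop("percentiles and log_rr must be equal-length vectors (>= 2)")
  }
  if (any(!is.finite(percentiles)) || any(!is.finite(log_rr))) {
    stop("non-finite curve coefficients")
  }
  if (any(percentiles < 0) || any(percentiles > 100) ||
      any(diff(percentiles) <= 0)) {
    stop("percentiles must be strictly ascending within [0, 100]")
  }
  structure(list(percentiles = percentiles, log_rr = log_rr,
                 age_group = age_group),
            class = "percentile_curve")
}

# Interpolator on the log-RR scale, clamped to the knot span. The
# Fritsch-Carlson monotone cubic can undershoot the bottom knot of a U by a
# few 1e-4 between knots; recentring against the continuous minimum (see
# erf_curve) absorbs this, keeping RR >= 1 - 1e-9 on U-shaped curves.
make_interp <- function(knots, log_rr, interpolation) {
  lo <- knots[1L]
  hi <- knots[length(knots)]
  restore <- function(out, t) {
    if (!is.null(dim(t))) dim(out) <- dim(t)
    out
  }
  if (interpolation == "linear") {
    function(t) {
      tc <- pmin(pmax(t, lo), hi)
      restore(stats::approx(knots, log_rr, xout = as.vector(tc),
                            method = "linear", ties = "ordered")$y, tc)
    }
  } else {
    f <- stats::splinefun(knots, log_rr, method = "monoH.FC")
    function(t) {
      tc <- pmin(pmax(t, lo), hi)
      restore(f(as.vector(tc)), tc)
    }
  }
}

#' Calibrated exposure-response curve in absolute temperature
#'
#' Constructs an age-group ERF from log-RR values at temperature knots. The
#' curve is recentred so that the relative risk at its minimum mortality
#' temperature (MMT) is exactly 1, the MMT being located by grid search over
#' the observed range. Interpolation between knots is monotone-shape-preserving
#' cubic on log RR by default (no spurious risk dips between knots); `"linear"`
#' is available for curves that are piecewise linear by construction.
#'
#' @param knot_temperatures Strictly ascending temperatures, degrees C.
#' @param log_rr_at_knots Log relative risk at the knots.
#' @param observed_range Length-2 `(min, max)` of the reference series.
#' @param age_group Age-group label.
#' @param interpolation `"monotone_cubic"` (default) or `"linear"`.
#' @param mmt_resolution Grid-search step for the MMT, degrees C.
#' @return An `erf_curve` with cached `mmt`, `rr_tmin`, `rr_tmax`.
#' @export
erf_curve <- function(knot_temperatures, log_rr_at_knots, observed_range,
                      age_group, interpolation = c("monotone_cubic", "linear"),
                      mmt_resolution = 0.1) {
  age_group <- match.arg(age_group, AGE_GROUPS)
  interpolation <- match.arg(interpolation)
  kt <- as.numeric(knot_temperatures)
  lrr <- as.numeric(log_rr_at_knots)
  if (length(kt) < 2L || length(kt) != length(lrr)) {
    stop("need >= 2 knots with matching log_rr values")
  }
  if (any(!is.finite(kt)) || any(!is.finite(lrr))) {
    stop("non-finite knots or coefficients")
  }
  if (any(diff(kt) <= 0)) stop("knot temperatures must be strictly ascending")
  observed_range <- as.numeric(observed_range)
  if (length(observed_range) != 2L || observed_range[1] >= observed_range[2]) {
    stop("observed_range must be (min, max) with min < max")
  }
  raw <- make_interp(kt, lrr, interpolation)
  mmt <- mmt_grid_search(raw, observed_range, mmt_resolution, knots = kt)
  # polish: the cubic interpolant can undershoot the grid/knot minimum by a
  # few 1e-5 between knots; recentring by the continuous minimum keeps
  # RR >= 1 - 1e-9 everywhere on a U-shaped curve
  opt <- stats::optimize(raw, c(max(observed_range[1], mmt - mmt_resolution),
                                min(observed_range[2], mmt + mmt_resolution)),
                         tol = 1e-9)
  if (opt$objective < raw(mmt) - 1e-12) mmt <- opt$minimum
  shift <- raw(mmt)
  lrr <- lrr - shift
  interp <- make_interp(kt, lrr, interpolation)
  structure(
    list(age_group = age_group, knot_temperatures = kt,
         log_rr_at_knots = lrr, observed_range = observed_range,
         interpolation = interpolation, interp = interp, mmt = mmt,
         rr_tmin = exp(interp(observed_range[1])),
         rr_tmax = exp(interp(observed_range[2]))),
    class = "erf_curve")
}

#' @export
print.erf_curve <- function(x, ...) {
  cat(sprintf(
    "<erf_curve> age %s: MMT %.1f C, RR(Tmin) %.3f, RR(Tmax) %.3f, range [%.1f, %.1f]\n",
    x$age_group, x$mmt, x$rr_tmin, x$rr_tmax,
    x$observed_range[1], x$observed_range[2]))
  invisible(x)
}

mmt_grid_search <- function(fun, range, resolution, knots = numeric()) {
  if (resolution <= 0) stop("resolution must be positive")
  grid <- seq(range[1], range[2], by = resolution)
  if (grid[length(grid)] < range[2]) grid <- c(grid, range[2])
  # knots inside the range join the candidate set: the interpolant is
  # monotone between knots, so a by-construction minimum at a knot is hit
  # exactly and recentring leaves RR(MMT) = 1 without residual
  grid <- sort(unique(c(grid, knots[knots >= range[1] & knots <= range[2]])))
  v <- fun(grid)
  # ties broken toward the warmer candidate (classifies fewer days as warm)
  grid[max(which(v <= min(v)))]
}

#' Translate a percentile curve to absolute temperature
#'
#' Knot temperatures are the empirical quantiles of the reference series at
#' the curve's percentiles (linear interpolation between order statistics,
#' `stats::quantile` type 7); the observed range is the series min/max; the
#' curve is recentred so RR at the located MMT equals 1.
#'
#' @param pc A [percentile_curve()].
#' @param reference_series Daily city-mean temperatures, length >= 100.
#' @param interpolation Passed to [erf_curve()].
#' @return An `erf_curve`.
#' @export
calibrate_to_temperature <- function(pc, reference_series,
                                     interpolation = "monotone_cubic") {
  stopifnot(inherits(pc, "percentile_curve"))
  x <- as.numeric(reference_series)
  if (length(x) < 100L) stop("reference series must have >= 100 days")
  if (any(!is.finite(x))) stop("non-finite temperatures in reference series")
  knots <- stats::quantile(x, pc$percentiles / 100, type = 7, names = FALSE)
  if (any(diff(knots) <= 0)) {
    stop("degenerate quantiles: reference series too concentrated for the ",
         "percentile grid")
  }
  erf_curve(knots, pc$log_rr, range(x), pc$age_group,
            interpolation = interpolation)
}

#' Evaluate relative risk at a temperature
#'
#' Interpolates log RR between knots and exponentiates. Outside the observed
#' range (and beyond the outermost knots) the boundary value is carried
#' constant. RR is strictly positive everywhere.
#'
#' @param curve An [erf_curve()].
#' @param t Temperature(s), degrees C.
#' @return Relative risk, same length as `t`.
#' @export
evaluate_rr <- function(curve, t) {
  stopifnot(inherits(curve, "erf_curve"))
  if (any(!is.finite(t))) stop("non-finite temperature")
  t <- pmin(pmax(t, curve$observed_range[1]), curve$observed_range[2])
  exp(curve$interp(t))
}

#' Locate the minimum mortality temperature
#'
#' Grid search for the temperature of lowest cumulative mortality risk over
#' the observed range, at the stated resolution; ties are broken toward the
#' warmer candidate.
#'
#' @param curve An [erf_curve()].
#' @param resolution Search step, degrees C (default 0.1).
#' @return MMT in degrees C.
#' @export
find_mmt <- function(curve, resolution = 0.1) {
  stopifnot(inherits(curve, "erf_curve"))
  mmt_grid_search(curve$interp, curve$observed_range, resolution,
                  knots = curve$knot_temperatures)
}

#' Relative risks at the observed extremes
#'
#' @param curve An [erf_curve()].
#' @return Named vector `c(rr_tmin = , rr_tmax = )`, RR at the coldest and
#'   warmest observed temperatures.
#' @export
extreme_rrs <- function(curve) {
  stopifnot(inherits(curve, "erf_curve"))
  c(rr_tmin = unname(evaluate_rr(curve, curve$observed_range[1])),
    rr_tmax = unname(evaluate_rr(curve, curve$observed_range[2])))
}

#' Exposure-response uncertainty ensemble
#'
#' @param central Central `erf_curve` (draw 0).
#' @param draws List of `erf_curve` draws sharing the age group.
#' @return An `erf_ensemble`.
#' @export
erf_ensemble <- function(central, draws) {
  stopifnot(inherits(central, "erf_curve"), length(draws) >= 1L)
  ages <- vapply(draws, function(d) d$age_group, "")
  if (!all(ages == central$age_group)) {
    stop("all draws must share the central curve's age group")
  }
  structure(list(central = central, draws = draws,
                 age_group = central$age_group),
            class = "erf_ensemble")
}

#' @export
print.erf_ensemble <- function(x, ...) {
  cat(sprintf("<erf_ensemble> age %s: central + %d draws\n",
              x$age_group, length(x$draws)))
  invisible(x)
}
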