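# Grid data model: planar equal-area analysis grid, static layers, daily
# temperature cubes, and the urban/rural/excluded analysis mask.
#
# Coordinate convention: cells are stored as flat vectors in row-major order,
# cell k (1-based) sits at row (k-1) %/% n_cols + 1, column (k-1) %% n_cols + 1,
# with cell-center semantics. All layers sharing a grid_spec have one shape.

#' Adult age groups and land classes used throughout
#'
#' `AGE_GROUPS`: the five adult age groups the exposure-response curves are
#' stratified by. `LAND_CLASSES`: the land-class codes of a land_class layer.
#'
#' @format Character vectors.
#' @export
AGE_GROUPS <- c("20-44", "45-64", "65-74", "75-84", "85+")

#' @rdname AGE_GROUPS
#' @format NULL
#' @export
LAND_CLASSES <- c("urban", "rural", "water")
LAYER_KINDS <- c("imperviousness_pct", "elevation_m", "population_count",
                 "land_class")
MASK_STATUS <- c("urban_included", "rural_included", "excluded_water",
                 "excluded_elevation")

#' Analysis grid geometry
#'
#' Defines a planar, equal-area analysis grid. Cells are square with side
#' `cell_size` metres (nominally 500 m); no map projection or latitude area
#' correction is applied, so all cells carry equal area weight.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param cell_size Cell side length in metres.
#' @param origin Planar (x, y) coordinate of the grid origin.
#' @return A `grid_spec` object.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size = 500, origin = c(0, 0)) {
  if (length(n_rows) != 1L || length(n_cols) != 1L ||
      is.na(n_rows) || is.na(n_cols) || n_rows < 1 || n_cols < 1 ||
      n_rows != round(n_rows) || n_cols != round(n_cols)) {
    stop("n_rows and n_cols must be positive integers")
  }
  if (length(cell_size) != 1L || !is.finite(cell_size) || cell_size <= 0) {
    stop("cell_size must be a positive number")
  }
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size = as.numeric(cell_size), origin = as.numeric(origin)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells, %.0f m\n",
              x$n_rows, x$n_cols, x$cell_size))
  invisible(x)
}

#' Number of cells in a grid
#' @param spec A [grid_spec()].
#' @return Integer cell count.
#' @export
n_cells <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  spec$n_rows * spec$n_cols
}

# row/column of flat cell indices (row-major)
cell_row <- function(spec, k) ((k - 1L) %/% spec$n_cols) + 1L
cell_col <- function(spec, k) ((k - 1L) %% spec$n_cols) + 1L

same_spec <- function(a, b) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    isTRUE(all.equal(a$cell_size, b$cell_size))
}

#' Static per-cell layer
#'
#' A single static field on the analysis grid. Supported kinds:
#' `imperviousness_pct` (sealed-surface share, 0-100), `elevation_m`,
#' `population_count` (non-negative adult inhabitants per cell) and
#' `land_class` (one of `"urban"`, `"rural"`, `"water"`).
#'
#' @param spec A [grid_spec()].
#' @param kind Layer kind, see Details.
#' @param values Per-cell values in row-major order (length `n_cells(spec)`).
#' @return A `static_layer` object.
#' @export
static_layer <- function(spec, kind, values) {
  stopifnot(inherits(spec, "grid_spec"))
  kind <- match.arg(kind, LAYER_KINDS)
  if (length(values) != n_cells(spec)) {
    stop(sprintf("values has length %d, expected %d cells",
                 length(values), n_cells(spec)))
  }
  if (kind == "land_class") {
    values <- as.character(values)
    bad <- setdiff(unique(values), LAND_CLASSES)
    if (length(bad)) {
      stop("unknown land class code(s): ", paste(bad, collapse = ", "))
    }
  } else {
    values <- as.numeric(values)
    if (anyNA(values) || any(!is.finite(values))) {
      stop("non-finite values in ", kind, " layer")
    }
    if (kind == "imperviousness_pct" &&
        (any(values < 0) || any(values > 100))) {
      stop("imperviousness_pct must lie in [0, 100]")
    }
    if (kind == "population_count" && any(values < 0)) {
      stop("population_count must be non-negative")
    }
  }
  structure(list(spec = spec, kind = kind, values = values),
            class = "static_layer")
}

#' @export
print.static_layer <- function(x, ...) {
  cat(sprintf("<static_layer> %s on %d x %d grid\n",
              x$kind, x$spec$n_rows, x$spec$n_cols))
  invisible(x)
}

#' Daily mean temperature cube
#'
#' Per-cell daily mean near-surface air temperature over a window of
#' consecutive calendar dates.
#'
#' @param spec A [grid_spec()].
#' @param dates `Date` vector, strictly increasing daily with no gaps.
#' @param values Numeric matrix, one row per date, one (row-major) column per
#'   cell, in degrees Celsius.
#' @return A `temperature_cube` object.
#' @export
temperature_cube <- function(spec, dates, values) {
  stopifnot(inherits(spec, "grid_spec"))
  dates <- as.Date(dates)
  if (length(dates) < 1L) stop("at least one date required")
  if (length(dates) > 1L && !all(diff(as.integer(dates)) == 1L)) {
    stop("dates must be strictly increasing consecutive days")
  }
  values <- as.matrix(values)
  if (nrow(values) != length(dates) || ncol(values) != n_cells(spec)) {
    stop(sprintf("values must be %d dates x %d cells",
                 length(dates), n_cells(spec)))
  }
  if (any(!is.finite(values))) stop("non-finite temperatures in cube")
  structure(list(spec = spec, dates = dates, values = values),
            class = "temperature_cube")
}

#' @export
print.temperature_cube <- function(x, ...) {
  cat(sprintf("<temperature_cube> %d days (%s to %s) on %d x %d grid\n",
              length(x$dates), min(x$dates), max(x$dates),
              x$spec$n_rows, x$spec$n_cols))
  invisible(x)
}

#' Re-grid a fine land-class layer by dominant class
#'
#' Aggregates a fine land-class layer to a coarser grid by an integer factor.
#' A coarse cell is classed `water` if any constituent fine cell is water
#' (only blocks containing no water feature count as land); otherwise it takes
#' the majority class among urban/rural fine cells, ties resolved to urban.
#'
#' @param fine_class_layer A land_class [static_layer()].
#' @param factor Positive integer block size; fine dimensions must be
#'   divisible by it.
#' @return A land_class `static_layer` on the coarse grid.
#' @export
regrid_dominant_class <- function(fine_class_layer, factor) {
  stopifnot(inherits(fine_class_layer, "static_layer"))
  if (fine_class_layer$kind != "land_class") {
    stop("regrid_dominant_class expects a land_class layer")
  }
  if (length(factor) != 1L || factor < 1 || factor != round(factor)) {
    stop("factor must be a positive integer")
  }
  factor <- as.integer(factor)
  fs <- fine_class_layer$spec
  if (fs$n_rows %% factor != 0L || fs$n_cols %% factor != 0L) {
    stop(sprintf("grid %d x %d not divisible by factor %d",
                 fs$n_rows, fs$n_cols, factor))
  }
  cs <- grid_spec(fs$n_rows %/% factor, fs$n_cols %/% factor,
                  cell_size = fs$cell_size * factor, origin = fs$origin)
  k <- seq_len(n_cells(fs))
  crow <- (cell_row(fs, k) - 1L) %/% factor
  ccol <- (cell_col(fs, k) - 1L) %/% factor
  cidx <- crow * cs$n_cols + ccol + 1L
  v <- fine_class_layer$values
  out <- character(n_cells(cs))
  n_water <- rowsum(as.numeric(v == "water"), cidx)[, 1L]
  n_urban <- rowsum(as.numeric(v == "urban"), cidx)[, 1L]
  n_rural <- rowsum(as.numeric(v == "rural"), cidx)[, 1L]
  out[n_water > 0] <- "water"
  land <- n_water == 0
  out[land & n_urban >= n_rural] <- "urban"
  out[land & n_urban < n_rural] <- "rural"
  static_layer(cs, "land_class", out)
}

#' Build the urban/rural/excluded analysis mask
#'
#' Implements the exclusion rules of the impact analysis: water cells are
#' excluded, and land cells whose elevation differs by more than `threshold`
#' metres from the domain population-weighted mean elevation are excluded.
#' The reference elevation is computed over all land cells (including cells
#' that the elevation rule subsequently excludes). Remaining cells keep their
#' urban or rural class as included strata.
#'
#' @param class_layer land_class [static_layer()].
#' @param elevation elevation_m [static_layer()].
#' @param population population_count [static_layer()] (weights for the
#'   reference elevation).
#' @param threshold Elevation tolerance in metres (default 100; `Inf`
#'   excludes only water).
#' @return An `analysis_mask` object with per-cell `status`.
#' @export
build_analysis_mask <- function(class_layer, elevation, population,
                                threshold = 100) {
  stopifnot(inherits(class_layer, "static_layer"),
            inherits(elevation, "static_layer"),
            inherits(population, "static_layer"))
  if (class_layer$kind != "land_class" || elevation$kind != "elevation_m" ||
      population$kind != "population_count") {
    stop("layer kinds must be land_class, elevation_m, population_count")
  }
  spec <- class_layer$spec
  if (!same_spec(spec, elevation$spec) || !same_spec(spec, population$spec)) {
    stop("all layers must share one grid_spec")
  }
  if (length(threshold) != 1L || is.na(threshold) || threshold < 0) {
    stop("threshold must be a non-negative number")
  }
  land <- class_layer$values != "water"
  w <- population$values[land]
  if (sum(w) <= 0) stop("total population over land cells is zero; ",
                        "population weights are degenerate")
  ref_elev <- sum(w * elevation$values[land]) / sum(w)
  status <- character(n_cells(spec))
  status[!land] <- "excluded_water"
  too_high <- land & abs(elevation$values - ref_elev) > threshold
  status[too_high] <- "excluded_elevation"
  keep <- land & !too_high
  status[keep & class_layer$values == "urban"] <- "urban_included"
  status[keep & class_layer$values == "rural"] <- "rural_included"
  structure(list(spec = spec, status = status, reference_elevation = ref_elev,
                 threshold = threshold),
            class = "analysis_mask")
}

#' @export
print.analysis_mask <- function(x, ...) {
  tab <- table(factor(x$status, levels = MASK_STATUS))
  cat(sprintf(
    "<analysis_mask> %d x %d: %d urban, %d rural, %d water, %d elevation-excluded\n",
    x$spec$n_rows, x$spec$n_cols, tab[["urban_included"]],
    tab[["rural_included"]], tab[["excluded_water"]],
    tab[["excluded_elevation"]]))
  invisible(x)
}

#' Included cell indices of a stratum
#'
#' @param mask An [build_analysis_mask()] result.
#' @param stratum `"urban"`, `"rural"` or `"all"` (both included strata).
#' @return Integer vector of flat cell indices.
#' @export
mask_cells <- function(mask, stratum = c("all", "urban", "rural")) {
  stopifnot(inherits(mask, "analysis_mask"))
  stratum <- match.arg(stratum)
  keep <- switch(stratum,
    urban = mask$status == "urban_included",
    rural = mask$status == "rural_included",
    all = mask$status %in% c("urban_included", "rural_included"))
  which(keep)
}

#' Weighted spatial mean over an included stratum
#'
#' Computes sum(w v) / sum(w) over the included cells of a stratum. Excluded
#' cells carry zero weight by construction. With `weights = NULL` all included
#' cells weigh equally (the individual-inhabitant perspective); passing the
#' population layer gives the population-weighted domain mean used for the
#' extreme-day temperature series.
#'
#' @param values A [static_layer()], or a numeric per-cell vector (e.g. one
#'   date slice of a cube).
#' @param weights A population_count [static_layer()], a numeric per-cell
#'   vector, or `NULL` for uniform weights.
#' @param mask An [build_analysis_mask()] result.
#' @param stratum `"urban"`, `"rural"` or `"all"`.
#' @return Scalar weighted mean.
#' @export
weighted_spatial_mean <- function(values, weights = NULL, mask,
                                  stratum = c("all", "urban", "rural")) {
  stratum <- match.arg(stratum)
  v <- if (inherits(values, "static_layer")) values$values else as.numeric(values)
  if (length(v) != n_cells(mask$spec)) {
    stop("values length does not match the mask grid")
  }
  idx <- mask_cells(mask, stratum)
  if (length(idx) == 0L) {
    stop(sprintf("stratum '%s' has no included cells", stratum))
  }
  if (is.null(weights)) {
    w <- rep(1, length(idx))
  } else {
    w <- if (inherits(weights, "static_layer")) weights$values else as.numeric(weights)
    if (length(w) != n_cells(mask$spec)) {
      stop("weights length does not match the mask grid")
    }
    w <- w[idx]
  }
  if (sum(w) <= 0) {
    stop(sprintf("stratum '%s' has non-positive total weight", stratum))
  }
  sum(w * v[idx]) / sum(w)
}
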