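# Plain-text file dialects. Grids travel as long-format CSV with a single
# metadata comment line; tables as ordinary header CSV (UTF-8, '.' decimal).
# Round-trips are value-exact for class layers and within 1e-6 for floats
# (values are written with 17 significant digits, so in practice exact).

meta_line <- function(type, spec, extra = character()) {
  kv <- c(sprintf("type=%s", type),
          sprintf("n_rows=%d", spec$n_rows),
          sprintf("n_cols=%d", spec$n_cols),
          sprintf("cell_size=%.17g", spec$cell_size),
          sprintf("origin_x=%.17g", spec$origin[1]),
          sprintf("origin_y=%.17g", spec$origin[2]),
          extra)
  paste("# uhimort", paste(kv, collapse = " "))
}

parse_meta <- function(path) {
  line <- readLines(path, n = 1L)
  if (!startsWith(line, "# uhimort ")) {
    stop("not a uhimort grid CSV (missing metadata line): ", path)
  }
  parts <- strsplit(sub("^# uhimort ", "", line), " ", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  out <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  out
}

spec_from_meta <- function(m) {
  grid_spec(as.integer(m[["n_rows"]]), as.integer(m[["n_cols"]]),
            cell_size = as.numeric(m[["cell_size"]]),
            origin = c(as.numeric(m[["origin_x"]]), as.numeric(m[["origin_y"]])))
}

#' Write / read a static layer as CSV
#'
#' Long-format CSV with columns `row,col,value` (1-based, row-major) preceded
#' by one `# uhimort` metadata comment line carrying the grid geometry and
#' layer kind.
#'
#' @param layer A [static_layer()].
#' @param path Output file path.
#' @return `write_layer_csv` returns `path` invisibly; `read_layer_csv`
#'   returns the reconstructed `static_layer`.
#' @export
write_layer_csv <- function(layer, path) {
  stopifnot(inherits(layer, "static_layer"))
  spec <- layer$spec
  k <- seq_len(n_cells(spec))
  df <- data.frame(row = cell_row(spec, k), col = cell_col(spec, k),
                   value = if (layer$kind == "land_class") layer$values
                           else sprintf("%.17g", layer$values))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(meta_line("static_layer", spec,
                       sprintf("kind=%s", layer$kind)), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_layer_csv
#' @export
read_layer_csv <- function(path) {
  m <- parse_meta(path)
  if (m[["type"]] != "static_layer") stop("not a static_layer CSV: ", path)
  spec <- spec_from_meta(m)
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = c("integer", "integer", "character"))
  k <- (df$row - 1L) * spec$n_cols + df$col
  if (!setequal(k, seq_len(n_cells(spec)))) {
    stop("layer CSV does not cover the grid exactly once: ", path)
  }
  vals <- character(n_cells(spec))
  vals[k] <- df$value
  if (m[["kind"]] != "land_class") vals <- as.numeric(vals)
  static_layer(spec, m[["kind"]], vals)
}

#' Write / read a daily temperature cube as CSV
#'
#' Long-format CSV with columns `date,row,col,tmean_c` preceded by one
#' `# uhimort` metadata comment line.
#'
#' @param cube A [temperature_cube()].
#' @param path Output file path.
#' @return `write_cube_csv` returns `path` invisibly; `read_cube_csv` returns
#'   the reconstructed `temperature_cube`.
#' @export
write_cube_csv <- function(cube, path) {
  stopifnot(inherits(cube, "temperature_cube"))
  spec <- cube$spec
  k <- seq_len(n_cells(spec))
  df <- data.frame(
    date = rep(as.character(cube$dates), times = length(k)),
    row = rep(cell_row(spec, k), each = length(cube$dates)),
    col = rep(cell_col(spec, k), each = length(cube$dates)),
    tmean_c = sprintf("%.17g", as.vector(cube$values)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(meta_line("temperature_cube", spec), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cube_csv
#' @export
read_cube_csv <- function(path) {
  m <- parse_meta(path)
  if (m[["type"]] != "temperature_cube") {
    stop("not a temperature_cube CSV: ", path)
  }
  spec <- spec_from_meta(m)
  df <- utils::read.csv(path, comment.char = "#",
                        colClasses = c("character", "integer", "integer",
                                       "numeric"))
  dates <- sort(unique(as.Date(df$date)))
  k <- (df$row - 1L) * spec$n_cols + df$col
  d <- match(as.Date(df$date), dates)
  vals <- matrix(NA_real_, nrow = length(dates), ncol = n_cells(spec))
  vals[cbind(d, k)] <- df$tmean_c
  if (anyNA(vals)) stop("cube CSV does not cover dates x cells: ", path)
  temperature_cube(spec, dates, vals)
}

#' Write / read exposure-response curve tables
#'
#' Percentile-space curve coefficients as plain CSV with columns
#' `city_id,age_group,percentile,log_rr,draw_index` (`draw_index` 0 is the
#' central curve).
#'
#' @param df Data frame with the columns above.
#' @param path File path.
#' @return `write_erf_csv` returns `path` invisibly; `read_erf_csv` the
#'   validated data frame.
#' @export
write_erf_csv <- function(df, path) {
  need <- c("city_id", "age_group", "percentile", "log_rr", "draw_index")
  if (!all(need %in% names(df))) {
    stop("ERF table needs columns: ", paste(need, collapse = ", "))
  }
  utils::write.csv(df[need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_erf_csv
#' @export
read_erf_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("city_id", "age_group", "percentile", "log_rr", "draw_index")
  if (!all(need %in% names(df))) {
    stop("ERF table needs columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(df$age_group), AGE_GROUPS)
  if (length(bad)) stop("unknown age group(s): ", paste(bad, collapse = ", "))
  df
}
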