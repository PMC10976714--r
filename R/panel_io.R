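# Balanced-panel container and long-format I/O.

#' Construct a balanced panel of series
#'
#' A `panel_series` holds an N x T matrix of finite values for N units
#' observed at T consecutive integer time points. It is the object all
#' convergence machinery consumes. Calendar years, when known, are kept as
#' metadata; the working time index is always 1..T because the log-t
#' regressor is log(t) and needs t >= 1.
#'
#' @param values numeric matrix, units in rows, time in columns.
#' @param units character vector of unit identifiers (defaults to rownames).
#' @param years optional integer vector of calendar years, one per column.
#' @param value_scale `"raw"` (strictly positive levels) or `"log"`
#'   (already log-transformed; no sign restriction).
#' @return An object of class `panel_series`.
#' @export
panel_series <- function(values, units = rownames(values), years = NULL,
                         value_scale = c("raw", "log")) {
  value_scale <- match.arg(value_scale)
  values <- as.matrix(values)
  if (is.null(units)) units <- paste0("U", seq_len(nrow(values)))
  units <- as.character(units)
  if (nrow(values) < 2L)
    stop("a panel needs at least 2 units, got ", nrow(values))
  if (ncol(values) < 7L)
    stop("a panel needs T >= 7 time points (trimmed log-t window), got ",
         ncol(values))
  if (length(units) != nrow(values))
    stop("length(units) must equal nrow(values)")
  if (anyDuplicated(units))
    stop("duplicate unit identifiers: ",
         paste(unique(units[duplicated(units)]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("panel values must be finite and non-missing (balanced panel)")
  if (value_scale == "raw" && any(values <= 0))
    stop("raw-scale panel must be strictly positive; ",
         "use log_transform() with an offset or supply value_scale = 'log'")
  if (!is.null(years)) {
    years <- as.integer(years)
    if (length(years) != ncol(values))
      stop("length(years) must equal ncol(values)")
    if (is.unsorted(years, strictly = TRUE))
      stop("years must be strictly increasing")
  }
  rownames(values) <- units
  colnames(values) <- if (!is.null(years)) years else seq_len(ncol(values))
  structure(list(units = units,
                 times = seq_len(ncol(values)),
                 years = years,
                 values = values,
                 value_scale = value_scale),
            class = "panel_series")
}

#' @export
print.panel_series <- function(x, ...) {
  cat(sprintf("panel_series: %d units x %d times (%s scale)\n",
              length(x$units), length(x$times), x$value_scale))
  if (!is.null(x$years))
    cat(sprintf("  years %d-%d\n", x$years[1], x$years[length(x$years)]))
  cat("  units:", paste(utils::head(x$units, 8), collapse = ", "),
      if (length(x$units) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.panel_series <- function(x) dim(x$values)

#' Subset a panel by unit
#'
#' @param p a `panel_series`.
#' @param units character vector of unit identifiers to keep (order kept
#'   as given).
#' @return A `panel_series` restricted to `units`. Needs at least 2 units.
#' @export
subset_units <- function(p, units) {
  stopifnot(inherits(p, "panel_series"))
  missing_u <- setdiff(units, p$units)
  if (length(missing_u))
    stop("unknown units: ", paste(missing_u, collapse = ", "))
  panel_series(p$values[units, , drop = FALSE], units = units,
               years = p$years, value_scale = p$value_scale)
}

#' Read a long-format panel table into a `panel_series`
#'
#' The file must be a header CSV with one row per (unit, time) pair. Time
#' values (calendar years) are mapped to the internal index 1..T in
#' increasing order. The panel must be balanced: every unit observed at
#' every time point.
#'
#' @param path CSV file path.
#' @param id_col,time_col,value_col column names; defaults follow the
#'   `unit,year,value` dialect.
#' @param value_scale scale tag passed to [panel_series()].
#' @return A `panel_series` sorted by unit then time.
#' @export
read_panel <- function(path, id_col = "unit", time_col = "year",
                       value_col = "value", value_scale = c("raw", "log")) {
  value_scale <- match.arg(value_scale)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c(id_col, time_col, value_col)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  long_to_panel(df[[id_col]], df[[time_col]], df[[value_col]],
                value_scale = value_scale)
}

# Shared core of read_panel() and balance(): long triplets -> matrix.
long_to_panel <- function(unit, time, value, value_scale = "raw") {
  unit <- as.character(unit)
  time <- as.integer(time)
  value <- suppressWarnings(as.numeric(value))
  bad <- which(!is.finite(value))
  if (length(bad))
    stop("non-numeric or missing values at rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  key <- paste(unit, time, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    stop("duplicate (unit, time) pair: ", gsub("\r", ", ", d))
  }
  units <- sort(unique(unit))
  times <- sort(unique(time))
  m <- matrix(NA_real_, length(units), length(times),
              dimnames = list(units, times))
  m[cbind(match(unit, units), match(time, times))] <- value
  if (anyNA(m)) {
    holes <- which(is.na(m), arr.ind = TRUE)
    msg <- paste(sprintf("(%s, %s)", units[holes[, 1]], times[holes[, 2]]),
                 collapse = ", ")
    stop("unbalanced panel; missing cells: ", msg)
  }
  yrs <- if (all(times == seq_along(times))) NULL else times
  panel_series(m, units = units, years = yrs, value_scale = value_scale)
}

#' Write a panel back to long CSV
#'
#' Inverse of [read_panel()]: emits `unit,year,value` rows (year falls back
#' to the 1..T index when no calendar mapping exists). Round-trips the
#' numeric payload bit-identically via full-precision formatting.
#'
#' @param p a `panel_series`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(p, path) {
  stopifnot(inherits(p, "panel_series"))
  yrs <- if (!is.null(p$years)) p$years else p$times
  df <- data.frame(unit = rep(p$units, times = length(yrs)),
                   year = rep(yrs, each = length(p$units)),
                   value = as.vector(p$values))
  df <- df[order(df$unit, df$year), ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("unit,year,value", con)
  writeLines(sprintf("%s,%d,%s", df$unit, df$year,
                     formatC(df$value, format = "g", digits = 17)), con)
  invisible(path)
}

#' Natural-log transform of a raw panel
#'
#' @param p a `panel_series` with `value_scale = "raw"`.
#' @param offset non-negative shift applied before the log (log(x + offset));
#'   the default 0 makes any non-positive entry a hard error, since silent
#'   offsets break cross-unit comparability.
#' @return A `panel_series` with `value_scale = "log"`.
#' @export
log_transform <- function(p, offset = 0) {
  stopifnot(inherits(p, "panel_series"))
  if (p$value_scale != "raw")
    stop("panel is already on the log scale")
  shifted <- p$values + offset
  if (any(shifted <= 0)) {
    bad <- which(shifted <= 0, arr.ind = TRUE)
    msg <- paste(sprintf("(%s, %s)", p$units[bad[, 1]],
                         colnames(p$values)[bad[, 2]]), collapse = ", ")
    stop("log undefined for non-positive entries at: ",
         utils::head(msg, 1),
         "; supply a positive `offset` to apply log(x + offset)")
  }
  q <- p
  q$values <- log(shifted)
  q$value_scale <- "log"
  q
}

#' Balance long records into a panel
#'
#' Handles gaps in a long table before constructing the balanced panel.
#' The conservative default drops any unit that is not fully observed;
#' `"interpolate_gaps_up_to_k"` linearly fills interior gaps of run length
#' at most `k` (leading/trailing gaps are never filled) and drops units
#' whose gaps exceed that. Every drop and fill is reported in the
#' `"balance_log"` attribute.
#'
#' @param records data.frame with unit, time and value columns.
#' @param policy `"drop_units_with_gaps"` (default) or
#'   `"interpolate_gaps_up_to_k"`.
#' @param k maximum interior gap run length to interpolate.
#' @param id_col,time_col,value_col column names.
#' @param value_scale scale tag for the result.
#' @return A `panel_series`; attribute `"balance_log"` records actions.
#' @export
balance <- function(records, policy = c("drop_units_with_gaps",
                                         "interpolate_gaps_up_to_k"),
                    k = 2, id_col = "unit", time_col = "year",
                    value_col = "value", value_scale = c("raw", "log")) {
  policy <- match.arg(policy)
  value_scale <- match.arg(value_scale)
  unit <- as.character(records[[id_col]])
  time <- as.integer(records[[time_col]])
  value <- as.numeric(records[[value_col]])
  units <- sort(unique(unit))
  times <- sort(unique(time))
  m <- matrix(NA_real_, length(units), length(times),
              dimnames = list(units, times))
  m[cbind(match(unit, units), match(time, times))] <- value

  log_lines <- character(0)
  keep <- rep(TRUE, length(units))
  for (i in seq_along(units)) {
    row <- m[i, ]
    if (!anyNA(row)) next
    if (policy == "drop_units_with_gaps") {
      keep[i] <- FALSE
      log_lines <- c(log_lines, sprintf(
        "dropped %s: %d missing cells", units[i], sum(is.na(row))))
      next
    }
    obs <- which(!is.na(row))
    interior <- is.na(row) & seq_along(row) > min(obs) &
      seq_along(row) < max(obs)
    runs <- rle(is.na(row))
    max_run <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
    if (all(is.na(row) == interior) && max_run <= k) {
      filled <- stats::approx(obs, row[obs], xout = seq_along(row))$y
      gap_idx <- which(is.na(row))
      m[i, ] <- filled
      log_lines <- c(log_lines, sprintf(
        "interpolated %s at %s", units[i],
        paste(times[gap_idx], collapse = ",")))
    } else {
      keep[i] <- FALSE
      log_lines <- c(log_lines, sprintf(
        "dropped %s: gaps exceed policy (max run %d, k = %d, or edge gap)",
        units[i], max_run, k))
    }
  }
  if (sum(keep) < 2L)
    stop("fewer than 2 units survive balancing; log:\n",
         paste(log_lines, collapse = "\n"))
  m <- m[keep, , drop = FALSE]
  yrs <- if (all(times == seq_along(times))) NULL else times
  out <- panel_series(m, units = units[keep], years = yrs,
                      value_scale = value_scale)
  attr(out, "balance_log") <- log_lines
  out
}

#' Read a unit-to-grouping membership table
#'
#' Expects a header CSV `unit,grouping` assigning each unit to exactly one
#' primary regional grouping (units that belong to several real-world
#' groupings must be resolved to one before this step).
#'
#' @param path CSV file path.
#' @return An object of class `membership`: a named character vector
#'   (names = units, values = grouping identifiers).
#' @export
read_membership <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("unit", "grouping"), names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  membership(stats::setNames(as.character(df$grouping),
                             as.character(df$unit)))
}

#' Construct a membership map
#'
#' @param map named character vector: names are units, values groupings.
#' @return An object of class `membership`.
#' @export
membership <- function(map) {
  if (is.null(names(map)) || any(names(map) == ""))
    stop("membership map must be named by unit")
  if (anyDuplicated(names(map)))
    stop("a unit may have only one primary grouping; duplicates: ",
         paste(unique(names(map)[duplicated(names(map))]), collapse = ", "))
  structure(as.character(stats::setNames(map, names(map))),
            names = names(map), class = "membership")
}
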