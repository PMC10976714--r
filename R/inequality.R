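# Gini coefficients within regional groupings, per year.

#' Gini coefficient
#'
#' Relative mean absolute difference: G = sum_ij |x_i - x_j| / (2 n^2 xbar),
#' without small-sample correction by default, so G lies in [0, 1) and is
#' invariant to scale and to replicating the population. The bias-corrected
#' variant multiplies by n/(n - 1).
#'
#' @param values non-negative numeric vector, length >= 2, at least one
#'   positive entry.
#' @param corrected apply the n/(n-1) small-sample correction.
#' @return The Gini coefficient.
#' @export
gini <- function(values, corrected = FALSE) {
  x <- as.numeric(values)
  n <- length(x)
  if (n < 2L) stop("need at least 2 values")
  if (any(!is.finite(x))) stop("values must be finite")
  if (any(x < 0)) stop("negative values not supported")
  if (mean(x) == 0) stop("all values are zero (mean zero): Gini undefined")
  # O(n log n) form via sorted values, equivalent to the pairwise sum
  xs <- sort(x)
  g <- 2 * sum(seq_len(n) * xs) / (n * sum(xs)) - (n + 1) / n
  if (corrected) g <- g * n / (n - 1)
  g
}

#' Per-grouping, per-year Gini panel
#'
#' Computes the Gini coefficient of the panel indicator over the members
#' of each regional grouping, for every time point: the dependent-variable
#' layout of the determinants stage. Groupings with fewer than 2 mapped
#' members are flagged and excluded. Gini is conventionally computed on
#' the raw (level) indicator; a warning is issued when the panel is on the
#' log scale.
#'
#' @param p a `panel_series` (raw scale expected).
#' @param m a `membership` map covering all panel units.
#' @param corrected passed to [gini()].
#' @return An object of class `gini_panel`: `table` (data.frame
#'   `grouping, year, gini, n_members`), `long` (country-level rows
#'   `unit, grouping, year, gini` where each unit-year carries its
#'   grouping's Gini -- the outcome layout of the mixed model), and
#'   `excluded` (groupings with < 2 members).
#' @export
rec_gini_panel <- function(p, m, corrected = FALSE) {
  stopifnot(inherits(p, "panel_series"), inherits(m, "membership"))
  unmapped <- setdiff(p$units, names(m))
  if (length(unmapped))
    stop("units without a grouping: ", paste(unmapped, collapse = ", "))
  if (p$value_scale == "log")
    warning("computing Gini on a log-scale panel; ",
            "the coefficient is usually taken on raw levels")
  grp <- unname(m[p$units])
  yrs <- if (!is.null(p$years)) p$years else p$times
  sizes <- table(grp)
  excluded <- names(sizes)[sizes < 2]
  if (length(excluded))
    message("excluding grouping(s) with < 2 members: ",
            paste(excluded, collapse = ", "))
  keep_g <- setdiff(sort(unique(grp)), excluded)

  rows <- list()
  for (g in keep_g) {
    members <- p$units[grp == g]
    vals <- p$values[members, , drop = FALSE]
    gv <- apply(vals, 2L, gini, corrected = corrected)
    rows[[g]] <- data.frame(grouping = g, year = yrs, gini = unname(gv),
                            n_members = length(members))
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  keep_units <- p$units[grp %in% keep_g]
  long <- data.frame(
    unit = rep(keep_units, each = length(yrs)),
    grouping = rep(unname(m[keep_units]), each = length(yrs)),
    year = rep(yrs, times = length(keep_units)))
  long$gini <- tab$gini[match(paste(long$grouping, long$year),
                              paste(tab$grouping, tab$year))]
  structure(list(table = tab, long = long, excluded = excluded),
            class = "gini_panel")
}

#' @export
print.gini_panel <- function(x, ...) {
  cat(sprintf("gini_panel: %d grouping(s) x %d year(s)\n",
              length(unique(x$table$grouping)),
              length(unique(x$table$year))))
  print(utils::head(x$table, 10))
  if (length(x$excluded))
    cat("excluded (< 2 members):", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Write a Gini panel to CSV
#'
#' Columns `grouping,year,gini,n_members`.
#'
#' @param gp a `gini_panel`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gini_panel <- function(gp, path) {
  stopifnot(inherits(gp, "gini_panel"))
  utils::write.csv(gp$table, path, row.names = FALSE)
  invisible(path)
}
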