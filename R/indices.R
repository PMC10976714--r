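# Composite indices by correlation screening and first-principal-component
# extraction.

#' Pearson correlation matrix with pairwise p-values
#'
#' Rows with any missing indicator are dropped before computing the
#' correlations (casewise deletion), so all entries share one sample size.
#'
#' @param table data.frame or matrix, observations x indicators (>= 2
#'   indicators, >= 3 complete rows).
#' @return An object of class `cor_matrix`: `r` (correlations, symmetric,
#'   unit diagonal), `p` (two-sided p-values, NA on the diagonal), `n`
#'   (complete observations used).
#' @export
correlation_matrix <- function(table) {
  m <- as.matrix(table)
  if (ncol(m) < 2L) stop("need at least 2 indicators")
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  if (n < 3L) stop("need at least 3 complete observations")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant indicator(s): ",
         paste(colnames(m)[sds == 0], collapse = ", "),
         " (correlation undefined)")
  r <- stats::cor(m)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- NA_real_
  structure(list(r = r, p = p, n = n), class = "cor_matrix")
}

#' First-principal-component composite index
#'
#' Eigendecomposition of the correlation matrix: components are sorted by
#' eigenvalue (descending), eigenvector signs are fixed so the first
#' indicator's loading on every component is non-negative (eigenvectors
#' are sign-ambiguous), and indicators with |loading| > 0.4 on component 1
#' are flagged as important contributors. When raw data are supplied,
#' component-1 scores are computed from the standardized indicators.
#'
#' @param x either a data table (observations x indicators) or a
#'   correlation matrix (symmetric, unit diagonal, PSD within tolerance).
#' @param tol PSD tolerance on the smallest eigenvalue (default 1e-8
#'   relative to the largest).
#' @return An object of class `composite_index`: `indicators`,
#'   `correlation`, `eigenvalues`, `proportions`, `cumulative`,
#'   `loadings` (unit-norm columns), `important` (|loading1| > 0.4),
#'   `scores` (component-1 scores, or `NULL` when only a correlation
#'   matrix was given), `rescaling`.
#' @export
pca_index <- function(x, tol = 1e-8) {
  is_cor <- is.matrix(x) && nrow(x) == ncol(x) &&
    isTRUE(all.equal(unname(diag(x)), rep(1, ncol(x)), tolerance = 1e-6)) &&
    isTRUE(all.equal(x, t(x), tolerance = 1e-6))
  if (is_cor) {
    R <- (x + t(x)) / 2
    scores_data <- NULL
  } else {
    m <- as.matrix(x)
    m <- m[stats::complete.cases(m), , drop = FALSE]
    R <- correlation_matrix(m)$r
    scores_data <- scale(m)
  }
  pnames <- colnames(R)
  if (is.null(pnames)) pnames <- paste0("V", seq_len(ncol(R)))
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < -tol * max(abs(e$values)))
    stop("matrix is not positive semi-definite within tolerance")
  vals <- pmax(e$values, 0)
  vecs <- e$vectors
  # sign convention: first indicator loads non-negatively on each component
  flip <- ifelse(vecs[1, ] < 0, -1, 1)
  vecs <- sweep(vecs, 2L, flip, "*")
  rownames(vecs) <- pnames
  colnames(vecs) <- paste0("Comp", seq_along(vals))
  scores <- if (!is.null(scores_data)) as.vector(scores_data %*% vecs[, 1])
  structure(list(indicators = pnames,
                 correlation = R,
                 eigenvalues = vals,
                 proportions = vals / sum(vals),
                 cumulative = cumsum(vals) / sum(vals),
                 loadings = vecs,
                 important = pnames[abs(vecs[, 1]) > 0.4],
                 scores = scores,
                 rescaling = "none"),
            class = "composite_index")
}

#' @export
print.composite_index <- function(x, ...) {
  cat(sprintf("composite_index on %d indicators\n", length(x$indicators)))
  tab <- data.frame(eigenvalue = round(x$eigenvalues, 3),
                    proportion = round(x$proportions, 3),
                    cumulative = round(x$cumulative, 3))
  rownames(tab) <- colnames(x$loadings)
  print(tab)
  cat("component-1 loadings:\n")
  print(round(x$loadings[, 1], 3))
  cat("important contributors (|loading| > 0.4):",
      paste(x$important, collapse = ", "), "\n")
  invisible(x)
}

#' Rescale composite-index scores
#'
#' Affine transforms only, so the ordering of observations is preserved.
#' `"shift_min_to_zero"` anchors the minimum score at 0, reproducing a
#' 0-anchored index scale.
#'
#' @param scores numeric vector of component scores.
#' @param mode `"none"` or `"shift_min_to_zero"`.
#' @return Rescaled scores.
#' @export
rescale_index <- function(scores, mode = c("none", "shift_min_to_zero")) {
  mode <- match.arg(mode)
  switch(mode,
         none = scores,
         shift_min_to_zero = scores - min(scores))
}

#' Eigenvalue table of a composite index
#'
#' @param idx a `composite_index`.
#' @return A data.frame with columns `component`, `eigenvalue`,
#'   `difference`, `proportion`, `cumulative` (the usual PCA summary
#'   layout).
#' @export
index_report <- function(idx) {
  stopifnot(inherits(idx, "composite_index"))
  k <- length(idx$eigenvalues)
  data.frame(component = paste0("Comp", seq_len(k)),
             eigenvalue = idx$eigenvalues,
             difference = c(-diff(idx$eigenvalues), NA_real_),
             proportion = idx$proportions,
             cumulative = idx$cumulative)
}
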