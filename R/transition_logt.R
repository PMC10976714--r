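# Relative transition paths, cross-sectional variance, and the log-t
# regression test of convergence.

#' Relative transition paths and cross-sectional variance
#'
#' For each unit i and time t the relative transition parameter is
#' h_it = X_it / mean_i(X_it): the unit's value relative to the panel
#' average, tracing its path against the cross-section. The cross-sectional
#' variance H_t = mean_i (h_it - 1)^2 decays to zero under convergence.
#'
#' @param p a `panel_series`.
#' @return An object of class `transition_result` with fields `h`
#'   (N x T matrix) and `H` (length-T vector).
#' @export
relative_transition <- function(p) {
  stopifnot(inherits(p, "panel_series"))
  X <- p$values
  cm <- colMeans(X)
  if (any(abs(cm) < .Machine$double.eps * 100))
    stop("cross-sectional mean is zero at some t; ",
         "relative transition undefined")
  h <- sweep(X, 2L, cm, "/")
  H <- colMeans((h - 1)^2)
  structure(list(h = h, H = H), class = "transition_result")
}

# Newey-West (Bartlett kernel) covariance for a small OLS fit.
# Xm: n x k design, u: residuals, lags: truncation lag L.
newey_west_vcov <- function(Xm, u, lags) {
  n <- nrow(Xm)
  g <- Xm * u
  S <- crossprod(g)
  if (lags > 0) {
    for (l in seq_len(min(lags, n - 1L))) {
      w <- 1 - l / (lags + 1)
      G <- crossprod(g[(l + 1):n, , drop = FALSE],
                     g[1:(n - l), , drop = FALSE])
      S <- S + w * (G + t(G))
    }
  }
  A <- solve(crossprod(Xm))
  A %*% S %*% A
}

#' Log-t regression test of convergence
#'
#' Regresses `log(H_1/H_t) - 2 log L(t)` on `log t` over the trimmed
#' window `t = t0..T` with `t0 = max(2, floor(r T))`, where H_t is the
#' cross-sectional variance of the relative transition paths and
#' `L(t) = log t` (the -2 log L(t) term penalizes the regressand under the
#' alternative). The slope estimates twice the speed-of-convergence
#' exponent (gamma = 2a). Inference uses a one-sided t-test with
#' Newey-West (Bartlett kernel) heteroskedasticity- and
#' autocorrelation-robust standard errors; the null of convergence is
#' rejected when t_gamma falls below the critical value (-1.65 by
#' default, the one-sided 5 percent point).
#'
#' @param p a `panel_series`.
#' @param r trimming fraction (default 0.3).
#' @param hac_lags Newey-West truncation lag; `NULL` selects
#'   `floor(4 (n/100)^(2/9))` on the window length n.
#' @param critical one-sided critical value (default -1.65).
#' @param L_form slow-variation function: `"log"` (L(t) = log t, default)
#'   or `"log1p"` (L(t) = log(t + 1), for sensitivity runs).
#' @return An object of class `logt_result`: `gamma_hat`, `intercept`,
#'   `se_gamma`, `t_gamma`, `r`, `window`, `critical`, `converged`,
#'   `residuals`, `hac_lags`, `n_units`.
#' @export
logt_regression <- function(p, r = 0.3, hac_lags = NULL, critical = -1.65,
                            L_form = c("log", "log1p")) {
  stopifnot(inherits(p, "panel_series"))
  logt_fit(p$values, r = r, hac_lags = hac_lags, critical = critical,
           L_form = match.arg(L_form))
}

# Matrix-level workhorse shared with the clustering loops (avoids
# re-validating panel invariants thousands of times in the sieve).
logt_fit <- function(X, r = 0.3, hac_lags = NULL, critical = -1.65,
                     L_form = "log") {
  N <- nrow(X)
  T_ <- ncol(X)
  cm <- colMeans(X)
  if (any(abs(cm) < .Machine$double.eps * 100))
    stop("cross-sectional mean is zero at some t")
  h <- sweep(X, 2L, cm, "/")
  H <- colMeans((h - 1)^2)

  t0 <- max(2L, as.integer(floor(r * T_)))
  if (T_ - t0 + 1L < 3L)
    stop("trimmed window [", t0, ", ", T_, "] has fewer than 3 points")
  win <- t0:T_
  if (H[1] <= 0 || any(H[win] <= 0))
    stop("degenerate panel: zero cross-sectional variance in the ",
         "regression window (all units identical)")

  Lt <- switch(L_form, log = log(win), log1p = log(win + 1))
  y <- log(H[1] / H[win]) - 2 * log(Lt)
  x <- log(win)
  n <- length(win)
  Xm <- cbind(1, x)
  cf <- solve(crossprod(Xm), crossprod(Xm, y))
  u <- as.vector(y - Xm %*% cf)

  lags <- if (is.null(hac_lags)) as.integer(floor(4 * (n / 100)^(2 / 9)))
          else as.integer(hac_lags)
  V <- newey_west_vcov(Xm, u, lags)
  se <- sqrt(max(V[2, 2], 0))
  gamma_hat <- cf[2]
  t_gamma <- if (se > 0) gamma_hat / se
             else if (gamma_hat == 0) 0 else sign(gamma_hat) * Inf

  structure(list(gamma_hat = unname(gamma_hat),
                 intercept = unname(cf[1]),
                 se_gamma = se,
                 t_gamma = unname(t_gamma),
                 r = r,
                 window = c(t0, T_),
                 critical = critical,
                 converged = unname(t_gamma > critical),
                 residuals = u,
                 hac_lags = lags,
                 n_units = N),
            class = "logt_result")
}

#' @export
print.logt_result <- function(x, ...) {
  cat("log-t regression test\n")
  cat(sprintf("  window t = %d..%d (r = %.2f), %d units, HAC lags %d\n",
              x$window[1], x$window[2], x$r, x$n_units, x$hac_lags))
  cat(sprintf("  gamma_hat = %.4f  (SE %.4f)  t = %.3f\n",
              x$gamma_hat, x$se_gamma, x$t_gamma))
  cat(sprintf("  %s (one-sided critical value %.2f)\n",
              if (x$converged) "convergence not rejected"
              else "convergence REJECTED", x$critical))
  invisible(x)
}

#' Flat report record for a log-t result
#'
#' Mirrors the usual coefficient / SE / t-stat table columns.
#'
#' @param res a `logt_result`.
#' @return A one-row data.frame: `coeff`, `se`, `t_stat`, `converged`,
#'   `n_units`, `window_start`, `window_end`.
#' @export
logt_report <- function(res) {
  stopifnot(inherits(res, "logt_result"))
  data.frame(coeff = res$gamma_hat, se = res$se_gamma,
             t_stat = res$t_gamma, converged = res$converged,
             n_units = res$n_units, window_start = res$window[1],
             window_end = res$window[2])
}

#' Serialize a log-t result to JSON
#'
#' @param res a `logt_result`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
logt_to_json <- function(res, path = NULL) {
  stopifnot(inherits(res, "logt_result"))
  obj <- res[c("gamma_hat", "intercept", "se_gamma", "t_gamma", "r",
               "window", "critical", "converged", "hac_lags", "n_units")]
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
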