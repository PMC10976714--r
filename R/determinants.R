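# Two-level random-intercept model, ICC, and robustness fits
# (within-grouping fixed effects, pooled OLS).

# Build and sanity-check the modelling frame shared by all three fits.
model_frame <- function(data, outcome, covariates, grouping = NULL) {
  need <- c(outcome, covariates, grouping)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  df <- data[, need, drop = FALSE]
  if (anyNA(df))
    stop("modelling frame has missing cells; balance/impute upstream")
  df
}

#' Two-level random-intercept linear mixed model
#'
#' Fits outcome ~ covariates + (1 | grouping) by REML (default) or ML
#' using lme4. Reports fixed effects with cluster-robust standard errors
#' (sandwich over groupings, using the closed-form inverse of the
#' random-intercept marginal covariance), the variance components, the
#' intra-class correlation ICC = sigma_u^2 / (sigma_u^2 + sigma_e^2), and
#' a likelihood-ratio statistic against pooled OLS (ML likelihoods; the
#' null puts sigma_u^2 on the boundary, so the reference distribution is
#' the 50:50 mixture of chi-squared 0 and 1).
#'
#' @param data long data.frame.
#' @param outcome,covariates,grouping column names.
#' @param method `"REML"` (default) or `"ML"`.
#' @param robust use cluster-robust (grouping-level) standard errors for
#'   the fixed effects; `FALSE` gives model-based SEs.
#' @return An object of class `mixed_model_result`: `coefficients`
#'   (data.frame estimate/se/z/p), `sigma_u2`, `sigma_e2`, `icc`,
#'   `logLik`, `logLik_ML`, `lr_stat`, `lr_p`, `boundary` (TRUE when the
#'   random-intercept variance collapsed to ~0), `method`, `n_obs`,
#'   `n_groups`, and the underlying `fit`.
#' @export
fit_mixed <- function(data, outcome, covariates, grouping,
                      method = c("REML", "ML"), robust = TRUE) {
  method <- match.arg(method)
  df <- model_frame(data, outcome, covariates, grouping)
  if (length(unique(df[[grouping]])) < 2L)
    stop("need at least 2 groupings")
  fml <- stats::as.formula(paste(
    outcome, "~", paste(covariates, collapse = " + "),
    "+ (1 |", grouping, ")"))
  fit <- lme4::lmer(fml, data = df, REML = (method == "REML"))

  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_u2 <- vc$vcov[vc$grp == grouping]
  sigma_e2 <- vc$vcov[vc$grp == "Residual"]
  boundary <- sigma_u2 < 1e-8 * max(sigma_e2, 1)
  beta <- lme4::fixef(fit)

  if (robust) {
    V <- cluster_robust_vcov_ri(df, outcome, covariates, grouping,
                                beta, sigma_u2, sigma_e2)
  } else {
    V <- as.matrix(stats::vcov(fit))
  }
  se <- sqrt(diag(V))
  z <- beta / se
  coefs <- data.frame(term = names(beta), estimate = unname(beta),
                      se = unname(se), z = unname(z),
                      p = unname(2 * stats::pnorm(-abs(z))))

  # LR against pooled OLS needs ML likelihoods on the same frame
  fit_ml <- if (method == "ML") fit else
    lme4::lmer(fml, data = df, REML = FALSE)
  ols <- stats::lm(stats::as.formula(paste(
    outcome, "~", paste(covariates, collapse = " + "))), data = df)
  ll_ml <- as.numeric(stats::logLik(fit_ml))
  ll_ols <- as.numeric(stats::logLik(ols))
  lr <- max(0, 2 * (ll_ml - ll_ols))
  lr_p <- 0.5 * stats::pchisq(lr, df = 1, lower.tail = FALSE)

  structure(list(coefficients = coefs, sigma_u2 = sigma_u2,
                 sigma_e2 = sigma_e2,
                 icc = sigma_u2 / (sigma_u2 + sigma_e2),
                 logLik = as.numeric(stats::logLik(fit)),
                 logLik_ML = ll_ml, logLik_OLS = ll_ols,
                 lr_stat = lr, lr_p = lr_p,
                 boundary = boundary, method = method, robust = robust,
                 n_obs = nrow(df),
                 n_groups = length(unique(df[[grouping]])),
                 fit = fit),
            class = "mixed_model_result")
}

# Cluster-robust sandwich for the GLS fixed effects of a random-intercept
# model. Per grouping j with n_j rows, the marginal covariance is
# V_j = s2e I + s2u J and its inverse is available in closed form
# (Sherman-Morrison), so no n x n solve is needed.
cluster_robust_vcov_ri <- function(df, outcome, covariates, grouping,
                                   beta, sigma_u2, sigma_e2) {
  X <- stats::model.matrix(stats::as.formula(
    paste("~", paste(covariates, collapse = " + "))), data = df)
  y <- df[[outcome]]
  g <- df[[grouping]]
  r <- y - as.vector(X %*% beta)
  k <- ncol(X)
  A <- matrix(0, k, k)
  B <- matrix(0, k, k)
  for (gi in unique(g)) {
    idx <- which(g == gi)
    Xj <- X[idx, , drop = FALSE]
    rj <- r[idx]
    nj <- length(idx)
    shrink <- sigma_u2 / (sigma_e2 + nj * sigma_u2)
    # V_j^{-1} z = (z - shrink * sum(z) 1) / s2e
    Vinv_X <- (Xj - shrink * matrix(colSums(Xj), nj, k, byrow = TRUE)) /
      sigma_e2
    Vinv_r <- (rj - shrink * sum(rj)) / sigma_e2
    A <- A + crossprod(Xj, Vinv_X)
    s <- crossprod(Xj, Vinv_r)
    B <- B + s %*% t(s)
  }
  Ainv <- solve(A)
  G <- length(unique(g))
  (G / (G - 1)) * Ainv %*% B %*% Ainv
}

#' @export
print.mixed_model_result <- function(x, ...) {
  cat(sprintf("two-level random-intercept model (%s, %s SEs)\n",
              x$method, if (x$robust) "cluster-robust" else "model-based"))
  cat(sprintf("  %d obs in %d groupings\n", x$n_obs, x$n_groups))
  print(transform(x$coefficients, estimate = round(estimate, 4),
                  se = round(se, 4), z = round(z, 2),
                  p = signif(p, 3)), row.names = FALSE)
  cat(sprintf("  sigma_u^2 = %.4f  sigma_e^2 = %.4f  ICC = %.3f%s\n",
              x$sigma_u2, x$sigma_e2, x$icc,
              if (x$boundary) "  [boundary fit: sigma_u^2 ~ 0]" else ""))
  cat(sprintf("  LR vs pooled OLS = %.2f (chibar2 p = %.3g)\n",
              x$lr_stat, x$lr_p))
  invisible(x)
}

#' Intra-class correlation of a fitted two-level model
#'
#' Share of outcome variance attributable to the grouping level:
#' sigma_u^2 / (sigma_u^2 + sigma_e^2).
#'
#' @param res a `mixed_model_result`.
#' @return ICC in [0, 1].
#' @export
icc <- function(res) {
  stopifnot(inherits(res, "mixed_model_result"))
  res$sigma_u2 / (res$sigma_u2 + res$sigma_e2)
}

#' Within-grouping fixed-effects fit
#'
#' Demeans outcome and covariates within each grouping, then runs OLS on
#' the demeaned frame with cluster-robust (grouping-level, CR1) standard
#' errors. Covariates constant within every grouping are dropped with a
#' warning (their within variation is zero).
#'
#' @inheritParams fit_mixed
#' @return An object of class `fe_model_result`: `coefficients`
#'   (term/estimate/se/t/p), `dropped`, `n_obs`, `n_groups`.
#' @export
fit_fixed_effects <- function(data, outcome, covariates, grouping) {
  df <- model_frame(data, outcome, covariates, grouping)
  g <- df[[grouping]]
  G <- length(unique(g))
  if (G < 2L)
    stop("fixed-effects fit needs at least 2 groupings ",
         "(with one grouping it collapses to a constant)")
  demean <- function(v) v - stats::ave(v, g)
  Xd <- vapply(covariates, function(cn) demean(df[[cn]]),
               numeric(nrow(df)))
  yd <- demean(df[[outcome]])
  keep <- apply(Xd, 2L, function(col) stats::sd(col) > 1e-12)
  if (!all(keep))
    warning("dropping covariate(s) constant within all groupings: ",
            paste(covariates[!keep], collapse = ", "))
  if (!any(keep)) stop("no covariate varies within groupings")
  Xd <- Xd[, keep, drop = FALSE]

  cf <- solve(crossprod(Xd), crossprod(Xd, yd))
  u <- yd - as.vector(Xd %*% cf)
  k <- ncol(Xd)
  n <- nrow(Xd)
  meat <- matrix(0, k, k)
  for (gi in unique(g)) {
    idx <- which(g == gi)
    s <- crossprod(Xd[idx, , drop = FALSE], u[idx])
    meat <- meat + s %*% t(s)
  }
  Ainv <- solve(crossprod(Xd))
  # CR1 small-sample factor
  V <- (G / (G - 1)) * ((n - 1) / (n - k)) * Ainv %*% meat %*% Ainv
  se <- sqrt(diag(V))
  tval <- as.vector(cf) / se
  coefs <- data.frame(term = colnames(Xd), estimate = as.vector(cf),
                      se = se, t = tval,
                      p = 2 * stats::pt(-abs(tval), df = G - 1))
  structure(list(coefficients = coefs,
                 dropped = covariates[!keep],
                 n_obs = n, n_groups = G),
            class = "fe_model_result")
}

#' Pooled OLS fit with heteroskedasticity-robust standard errors
#'
#' Plain OLS of the outcome on the covariates (plus intercept) with HC1
#' robust standard errors, R-squared and the overall F-test. Rank
#' deficiency is a hard error naming the collinear columns.
#'
#' @inheritParams fit_mixed
#' @return An object of class `ols_model_result`: `coefficients`
#'   (term/estimate/se/t/p), `r_squared`, `f_stat`, `f_p`, `n_obs`.
#' @export
fit_pooled_ols <- function(data, outcome, covariates) {
  df <- model_frame(data, outcome, covariates)
  X <- stats::model.matrix(stats::as.formula(
    paste("~", paste(covariates, collapse = " + "))), data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  y <- df[[outcome]]
  cf <- qr.coef(qrX, y)
  u <- y - as.vector(X %*% cf)
  n <- nrow(X); k <- ncol(X)
  Ainv <- solve(crossprod(X))
  meat <- crossprod(X * u)
  V <- (n / (n - k)) * Ainv %*% meat %*% Ainv  # HC1
  se <- sqrt(diag(V))
  tval <- cf / se
  tss <- sum((y - mean(y))^2)
  rss <- sum(u^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  f_stat <- if (rss > 0)
    ((tss - rss) / (k - 1)) / (rss / (n - k)) else Inf
  f_p <- stats::pf(f_stat, k - 1, n - k, lower.tail = FALSE)
  coefs <- data.frame(term = colnames(X), estimate = unname(cf),
                      se = se, t = unname(tval),
                      p = unname(2 * stats::pt(-abs(tval), df = n - k)))
  structure(list(coefficients = coefs, r_squared = r2,
                 f_stat = f_stat, f_p = f_p, n_obs = n),
            class = "ols_model_result")
}

#' Three-column comparison of the mixed, fixed-effects and pooled fits
#'
#' @param mixed,fe,ols results of the three fitting functions on the same
#'   frame.
#' @return A data.frame with one row per covariate and estimate/SE columns
#'   per model.
#' @export
model_comparison <- function(mixed, fe, ols) {
  terms <- union(union(mixed$coefficients$term, fe$coefficients$term),
                 ols$coefficients$term)
  pick <- function(res, col) {
    res$coefficients[[col]][match(terms, res$coefficients$term)]
  }
  data.frame(term = terms,
             mlm_est = pick(mixed, "estimate"), mlm_se = pick(mixed, "se"),
             fe_est = pick(fe, "estimate"), fe_se = pick(fe, "se"),
             ols_est = pick(ols, "estimate"), ols_se = pick(ols, "se"))
}
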