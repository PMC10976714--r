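# Seeded generators: the semi-parametric loading process behind the
# convergence test, and two-level grouped covariate/outcome panels for the
# determinants stage.

#' Specify the semi-parametric panel generating process
#'
#' The generator builds X_it = delta_it * mu_t where the loading
#' delta_it = delta_i + theta_i * e_it / (L(t) t^a) decays toward the
#' unit's limiting loading delta_i at speed a (e_it iid standard normal,
#' L a slowly varying function). Units sharing a delta_i form a planted
#' convergence club. Divergent units instead follow a linearly drifting
#' loading delta_i + b t/T (plus the same decaying noise), so they never
#' settle on any club's path.
#'
#' @param delta named numeric vector: limiting loading per unit; units
#'   with equal delta form one planted club. Names default to U01, U02, ...
#' @param T_len number of time points (>= 7).
#' @param theta idiosyncratic scale (scalar or per-unit vector, >= 0).
#' @param a decay exponent (speed of convergence); the log-t slope
#'   estimates 2a.
#' @param divergent named numeric vector of drift slopes b for divergent
#'   units (names must be a subset of `names(delta)`); empty by default.
#' @param L_form slow-variation function used in the noise denominator:
#'   `"log1p"` (L(t) = log(t + 1), default -- finite at t = 1) or `"log"`
#'   (L(t) = log t; the t = 1 noise term is then set to zero).
#' @param mu_form common-trend law: `"linear"` (mu_t = 1 + drift * t,
#'   default) or `"rw"` (random walk with drift, positive-clamped).
#' @param mu_drift drift of the common trend (default 0.02 per period).
#' @param seed integer RNG seed used by [simulate_panel()].
#' @return An object of class `dgp_spec`.
#' @export
dgp_spec <- function(delta, T_len, theta = 0.05, a = 0.5,
                     divergent = numeric(0),
                     L_form = c("log1p", "log"),
                     mu_form = c("linear", "rw"),
                     mu_drift = 0.02, seed = 1L) {
  L_form <- match.arg(L_form)
  mu_form <- match.arg(mu_form)
  nm <- names(delta)
  if (is.null(nm)) nm <- rep("", length(delta))
  blank <- !nzchar(nm)
  nm[blank] <- sprintf("U%02d", which(blank))
  if (anyDuplicated(nm))
    stop("duplicate unit names in delta: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(delta) <- nm
  N <- length(delta)
  if (N < 2L) stop("need at least 2 units")
  if (T_len < 7L) stop("need T >= 7")
  theta <- rep_len(theta, N)
  if (any(theta < 0)) stop("theta must be >= 0")
  names(theta) <- names(delta)
  if (length(divergent) && !all(names(divergent) %in% names(delta)))
    stop("divergent names must be a subset of the units")
  structure(list(delta = delta, N = N, T_len = as.integer(T_len),
                 theta = theta, a = a, divergent = divergent,
                 L_form = L_form, mu_form = mu_form, mu_drift = mu_drift,
                 seed = as.integer(seed)),
            class = "dgp_spec")
}

#' Simulate a panel from the semi-parametric loading process
#'
#' Draws the noise e_it iid N(0, 1) under `spec$seed`, builds the loadings
#' and the common trend, and emits X_it = delta_it * mu_t together with the
#' planted club partition for use as an oracle. Output is reproducible:
#' the same spec (including seed) gives a bit-identical panel.
#'
#' @param spec a `dgp_spec`.
#' @param value_scale scale tag for the emitted panel. The default
#'   `"log"` treats X as already being on the analysis (log) scale, as the
#'   convergence machinery assumes; `"raw"` additionally enforces strict
#'   positivity and errors if a loading crosses zero.
#' @return A list: `panel` (a `panel_series`), `partition` (list of
#'   planted clubs as character vectors, plus `divergent`), `spec`.
#' @export
simulate_panel <- function(spec, value_scale = c("log", "raw")) {
  stopifnot(inherits(spec, "dgp_spec"))
  value_scale <- match.arg(value_scale)
  N <- spec$N; T_ <- spec$T_len
  set.seed(spec$seed)

  tt <- seq_len(T_)
  Lt <- switch(spec$L_form, log1p = log(tt + 1), log = log(tt))
  denom <- Lt * tt^spec$a
  denom[!is.finite(denom) | denom == 0] <- Inf  # kills the t = 1 noise
                                                # when L(t) = log t
  e <- matrix(stats::rnorm(N * T_), N, T_)
  delta_it <- spec$delta + spec$theta * e / rep(denom, each = N)

  if (length(spec$divergent)) {
    idx <- match(names(spec$divergent), names(spec$delta))
    drift <- outer(spec$divergent, tt / T_)
    delta_it[idx, ] <- delta_it[idx, ] + drift
  }

  mu <- switch(spec$mu_form,
    linear = 1 + spec$mu_drift * tt,
    rw = {
      steps <- stats::rnorm(T_, mean = spec$mu_drift, sd = 0.05)
      pmax(1 + cumsum(steps), 0.05)
    })
  X <- sweep(delta_it, 2L, mu, "*")
  rownames(X) <- names(spec$delta)

  if (value_scale == "raw" && any(X <= 0))
    stop("loading crossed zero: the panel is not strictly positive; ",
         "lower theta, raise delta, or keep value_scale = 'log'")

  clubs <- split(names(spec$delta)[!names(spec$delta) %in%
                                     names(spec$divergent)],
                 spec$delta[!names(spec$delta) %in% names(spec$divergent)])
  clubs <- clubs[order(-as.numeric(names(clubs)))]  # highest loading first
  names(clubs) <- NULL
  list(panel = panel_series(X, value_scale = value_scale),
       partition = list(clubs = lapply(clubs, as.character),
                        divergent = names(spec$divergent)),
       spec = spec)
}

#' Specify a two-level grouped covariate/outcome dataset
#'
#' Generates country-in-grouping style long data: covariates drawn
#' independently (log-normal by default, so their logs are standard
#' normal), outcome = intercept + covariates x beta + grouping random
#' intercept + residual noise. The planted intra-class correlation is
#' sigma_u^2 / (sigma_u^2 + sigma_e^2).
#'
#' @param G number of groupings (>= 2).
#' @param units_per_group units per grouping.
#' @param T_len time points per unit.
#' @param beta named numeric vector of fixed-effect slopes; its length
#'   sets the number of covariates. Default: 3 covariates.
#' @param intercept fixed intercept (default 0).
#' @param sigma_u random-intercept standard deviation (grouping level).
#' @param sigma_e residual standard deviation.
#' @param covariate_law `"lognormal"` (covariates exp(N(0,1)); regressions
#'   use their logs) or `"normal"`.
#' @param seed integer RNG seed used by [simulate_rec_dataset()].
#' @return An object of class `rec_spec`.
#' @export
rec_spec <- function(G, units_per_group, T_len = 1L,
                     beta = c(x1 = 0.5, x2 = -0.3, x3 = 0.2),
                     intercept = 0, sigma_u = 1, sigma_e = 1,
                     covariate_law = c("lognormal", "normal"), seed = 1L) {
  covariate_law <- match.arg(covariate_law)
  if (G < 2L) stop("need at least 2 groupings")
  if (sigma_u < 0 || sigma_e < 0) stop("standard deviations must be >= 0")
  if (is.null(names(beta))) names(beta) <- paste0("x", seq_along(beta))
  structure(list(G = as.integer(G),
                 units_per_group = as.integer(units_per_group),
                 T_len = as.integer(T_len), beta = beta,
                 intercept = intercept, sigma_u = sigma_u,
                 sigma_e = sigma_e, covariate_law = covariate_law,
                 seed = as.integer(seed)),
            class = "rec_spec")
}

#' Simulate a two-level grouped dataset
#'
#' @param spec a `rec_spec`.
#' @return A list: `data` (long data.frame with `unit`, `grouping`,
#'   `time`, one column per covariate -- already on the modelling (log)
#'   scale when the law is log-normal -- and outcome `y`) and `truth`
#'   (planted `beta`, `intercept`, `sigma_u`, `sigma_e`, `icc`, and the
#'   realized grouping intercepts `u`).
#' @export
simulate_rec_dataset <- function(spec) {
  stopifnot(inherits(spec, "rec_spec"))
  set.seed(spec$seed)
  G <- spec$G; n <- spec$units_per_group; T_ <- spec$T_len
  p <- length(spec$beta)
  n_obs <- G * n * T_

  grouping <- rep(sprintf("G%02d", seq_len(G)), each = n * T_)
  unit <- rep(sprintf("G%02d_U%02d", rep(seq_len(G), each = n),
                      rep(seq_len(n), times = G)), each = T_)
  time <- rep(seq_len(T_), times = G * n)

  # "lognormal": the raw indicator is exp(N(0,1)) and the modelling frame
  # carries its log, i.e. a standard normal -- identical draws to the
  # "normal" law; the tag only documents the raw-scale interpretation.
  Xc <- matrix(stats::rnorm(n_obs * p), n_obs, p)
  colnames(Xc) <- names(spec$beta)

  u <- stats::rnorm(G, 0, spec$sigma_u)
  names(u) <- sprintf("G%02d", seq_len(G))
  eps <- stats::rnorm(n_obs, 0, spec$sigma_e)
  y <- spec$intercept + as.vector(Xc %*% spec$beta) +
    u[match(grouping, names(u))] + eps

  icc_true <- if (spec$sigma_u == 0 && spec$sigma_e == 0) 0 else
    spec$sigma_u^2 / (spec$sigma_u^2 + spec$sigma_e^2)
  list(data = data.frame(unit = unit, grouping = grouping, time = time,
                         Xc, y = unname(y), stringsAsFactors = FALSE),
       truth = list(beta = spec$beta, intercept = spec$intercept,
                    sigma_u = spec$sigma_u, sigma_e = spec$sigma_e,
                    icc = icc_true, u = u))
}

#' Write a simulated panel and its ground truth to disk
#'
#' Emits the same long CSV dialect [read_panel()] consumes, plus a JSON
#' sidecar with the planted partition and generator parameters.
#'
#' @param sim result of [simulate_panel()].
#' @param csv_path,json_path output file paths.
#' @return `csv_path`, invisibly.
#' @export
write_simulation <- function(sim, csv_path, json_path = NULL) {
  write_panel(sim$panel, csv_path)
  if (!is.null(json_path)) {
    truth <- list(partition = sim$partition,
                  spec = unclass(sim$spec))
    writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA),
               json_path)
  }
  invisible(csv_path)
}
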