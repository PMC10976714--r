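# Shared medium-size simulated dataset for the fitting tests.
det_sim <- simulate_rec_dataset(rec_spec(
  G = 12, units_per_group = 8, T_len = 10,
  beta = c(x1 = 0.5, x2 = -0.3, x3 = 0.2), intercept = 1,
  sigma_u = sqrt(3), sigma_e = 1, seed = 101))
det_covs <- c("x1", "x2", "x3")

test_that("fit_mixed recovers planted fixed effects and variances", {
  fm <- fit_mixed(det_sim$data, "y", det_covs, "grouping")
  est <- fm$coefficients
  for (b in det_covs) {
    row <- est[est$term == b, ]
    expect_lt(abs(row$estimate - det_sim$truth$beta[[b]]), 3 * row$se)
  }
  expect_equal(fm$sigma_e2, 1, tolerance = 0.2)
  expect_false(fm$boundary)
  expect_equal(fm$n_groups, 12)
  expect_equal(fm$n_obs, 12 * 8 * 10)
})

test_that("icc arithmetic and bounds are exact", {
  fm <- fit_mixed(det_sim$data, "y", det_covs, "grouping")
  expect_equal(icc(fm), fm$sigma_u2 / (fm$sigma_u2 + fm$sigma_e2))
  expect_gte(icc(fm), 0)
  expect_lte(icc(fm), 1)

  # synthetic results exercise the formula directly
  mk <- function(u2, e2) structure(list(sigma_u2 = u2, sigma_e2 = e2),
                                   class = "mixed_model_result")
  expect_equal(icc(mk(0, 1)), 0)
  expect_equal(icc(mk(3, 1)), 0.75)
  expect_equal(icc(mk(2, 2)), 0.5)
})

test_that("with sigma_u = 0 planted, the mixed fit collapses to OLS", {
  sim0 <- simulate_rec_dataset(rec_spec(
    G = 10, units_per_group = 10, T_len = 5,
    beta = c(x1 = 0.5, x2 = -0.3), intercept = 2,
    sigma_u = 0, sigma_e = 1, seed = 102))
  fm <- fit_mixed(sim0$data, "y", c("x1", "x2"), "grouping")
  expect_true(fm$boundary)
  expect_lt(icc(fm), 0.01)
  ols <- fit_pooled_ols(sim0$data, "y", c("x1", "x2"))
  expect_equal(fm$coefficients$estimate, ols$coefficients$estimate,
               tolerance = 1e-6)
})

test_that("mixed-model ML likelihood dominates pooled OLS (nesting)", {
  fm <- fit_mixed(det_sim$data, "y", det_covs, "grouping", method = "ML")
  expect_gte(fm$logLik_ML, fm$logLik_OLS - 1e-6)
  expect_gte(fm$lr_stat, 0)
})

test_that("permuting grouping labels destroys the ICC", {
  set.seed(103)
  shuffled <- det_sim$data
  shuffled$grouping <- sample(shuffled$grouping)
  fm <- fit_mixed(shuffled, "y", det_covs, "grouping")
  expect_lt(icc(fm), 0.02)
})

test_that("fixed-effects fit recovers beta and demeans correctly", {
  fe <- fit_fixed_effects(det_sim$data, "y", det_covs, "grouping")
  for (b in det_covs) {
    row <- fe$coefficients[fe$coefficients$term == b, ]
    expect_lt(abs(row$estimate - det_sim$truth$beta[[b]]), 3 * row$se)
  }

  # demeaned covariate means are zero within groups (checked via a
  # reconstruction of the demeaning used by the fit)
  g <- det_sim$data$grouping
  xd <- det_sim$data$x1 - ave(det_sim$data$x1, g)
  expect_equal(max(abs(tapply(xd, g, mean))), 0, tolerance = 1e-12)

  # a covariate constant within all groupings is dropped
  df2 <- det_sim$data
  df2$const_in_g <- as.numeric(factor(df2$grouping))
  expect_warning(
    fe2 <- fit_fixed_effects(df2, "y", c(det_covs, "const_in_g"),
                             "grouping"),
    "constant within")
  expect_false("const_in_g" %in% fe2$coefficients$term)

  # single grouping is rejected
  df1 <- det_sim$data[det_sim$data$grouping == "G01", ]
  expect_error(fit_fixed_effects(df1, "y", det_covs, "grouping"),
               "at least 2 groupings")
})

test_that("pooled OLS is exact on noise-free data and robust otherwise", {
  sim0 <- simulate_rec_dataset(rec_spec(
    G = 5, units_per_group = 6, T_len = 3,
    beta = c(x1 = 2, x2 = -1), intercept = 4,
    sigma_u = 0, sigma_e = 0, seed = 104))
  ols0 <- fit_pooled_ols(sim0$data, "y", c("x1", "x2"))
  est <- setNames(ols0$coefficients$estimate, ols0$coefficients$term)
  expect_equal(unname(est["(Intercept)"]), 4, tolerance = 1e-10)
  expect_equal(unname(est["x1"]), 2, tolerance = 1e-10)
  expect_equal(unname(est["x2"]), -1, tolerance = 1e-10)
  expect_equal(ols0$r_squared, 1, tolerance = 1e-12)

  ols <- fit_pooled_ols(det_sim$data, "y", det_covs)
  for (b in det_covs) {
    row <- ols$coefficients[ols$coefficients$term == b, ]
    expect_lt(abs(row$estimate - det_sim$truth$beta[[b]]), 4 * row$se)
  }
  expect_lt(ols$f_p, 1e-10)

  # rank deficiency errors with the collinear column named
  dfc <- det_sim$data
  dfc$x1_copy <- dfc$x1
  expect_error(fit_pooled_ols(dfc, "y", c(det_covs, "x1_copy")),
               "x1_copy")
})

test_that("ICC bounds hold across many random fits (property)", {
  for (i in 1:25) {
    sim <- simulate_rec_dataset(rec_spec(
      G = 6, units_per_group = 4, T_len = 2,
      beta = c(x1 = runif(1, -1, 1)),
      sigma_u = runif(1, 0, 2), sigma_e = runif(1, 0.2, 2),
      seed = 500 + i))
    fm <- suppressMessages(fit_mixed(sim$data, "y", "x1", "grouping"))
    expect_gte(icc(fm), 0)
    expect_lte(icc(fm), 1)
  }
})

test_that("model_comparison lines up the three columns", {
  fm <- fit_mixed(det_sim$data, "y", det_covs, "grouping")
  fe <- fit_fixed_effects(det_sim$data, "y", det_covs, "grouping")
  ols <- fit_pooled_ols(det_sim$data, "y", det_covs)
  cmp <- model_comparison(fm, fe, ols)
  expect_true(all(det_covs %in% cmp$term))
  r <- cmp[cmp$term == "x1", ]
  expect_equal(r$mlm_est,
               fm$coefficients$estimate[fm$coefficients$term == "x1"])
  expect_equal(r$fe_est,
               fe$coefficients$estimate[fe$coefficients$term == "x1"])
  # FE has no intercept row
  expect_true(is.na(cmp$fe_est[cmp$term == "(Intercept)"]))
})
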