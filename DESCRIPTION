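Package: oopclubs
Title: Club Convergence and Determinants of Out-of-Pocket Health
    Expenditure Panels
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying convergence of health-financing indicators
    across country panels. Implements the log-t regression test of
    convergence with heteroskedasticity- and autocorrelation-robust
    inference, the core-group clustering algorithm that identifies
    convergence clubs, and the adjacent-club merging step. A second stage
    relates within-region inequality (Gini coefficients of the indicator,
    computed per regional grouping and year) to country-level macro
    covariates through a two-level random-intercept linear mixed model
    with intra-class correlation diagnostics, alongside fixed-effect and
    pooled OLS robustness fits. Composite governance and ICT indices are
    built by first-principal-component extraction from correlation
    matrices. A seeded synthetic-data generator emulates the
    semi-parametric loading process assumed by the convergence test and
    the two-level covariate/outcome structure of the determinants stage,
    so the whole pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    lme4
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
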