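---
title: "Methods: club convergence and the determinants of within-grouping inequality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: club convergence and the determinants of within-grouping inequality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oopclubs)
```

## Scope

`oopclubs` studies convergence of health-financing indicators — out-of-pocket
health expenditure (OOPHE) per capita, or its share of total health
expenditure — across a balanced panel of countries, and then models the
determinants of within-regional-grouping inequality in those indicators.
This vignette records the statistical model, the parameters that matter,
the numerical and design choices that were genuinely open, and what the
test suite does and does not establish.

## The convergence model

Each unit's (log) series is decomposed as $X_{it} = \delta_{it}\,\mu_t$:
a time-varying common trend $\mu_t$ scaled by a unit-specific loading
$\delta_{it}$. Nothing in this decomposition is separately estimated;
the machinery works entirely through ratios, which cancel $\mu_t$:

$$h_{it} = \frac{X_{it}}{N^{-1}\sum_i X_{it}}, \qquad
  H_t = \frac{1}{N}\sum_i (h_{it}-1)^2 .$$

$h_{it}$ — the *relative transition parameter* — is a unit's path
relative to the panel average; its cross-sectional mean is identically 1
(asserted to 1e-12 in the tests). Under convergence all loadings
approach a common constant, so $h_{it}\to 1$ and $H_t\to 0$.

### The log-t regression

The test regresses, over the trimmed window $t = t_0,\dots,T$ with
$t_0 = \max(2, \lfloor rT\rfloor)$,

$$\log\frac{H_1}{H_t} - 2\log L(t) \;=\; \hat Q + \hat\gamma \log t + u_t,
  \qquad L(t) = \log t,$$

and rejects convergence when the one-sided HAC t-statistic of
$\hat\gamma$ falls below the critical value (default $-1.65$). Under the
semi-parametric loading law

$$\delta_{it} = \delta_i + \frac{\theta_i\, e_{it}}{L(t)\,t^{a}},
  \qquad e_{it}\ \mathrm{iid}\ N(0,1),$$

the slope estimates twice the speed of convergence, $\gamma = 2a$; the
Monte-Carlo tests confirm $\mathbb{E}[\hat\gamma]\approx 2a$ within
$\pm 0.2$ for $a \in \{0.25, 0.5, 1.0\}$ at $T = 100$, $N = 20$.

Parameters and defaults:

* **Trimming `r = 0.3`.** The published simulation evidence behind the
  methodology shows this fraction balances size and power; the window
  start is clamped to $t \ge 2$ so $\log\log t$ is defined.
* **`L(t) = log t`** exactly as the regression is printed; `log(t+1)` is
  available for sensitivity runs.
* **HAC inference.** The source methodology asks only for inference
  "robust to heteroscedasticity and autocorrelation". We use Newey–West
  with a Bartlett kernel and automatic lag
  $\lfloor 4 (n/100)^{2/9}\rfloor$ on the window length $n$ — the
  standard default in implementations of this test — overridable via
  `hac_lags`. The kernel sum is verified in tests against an independent
  $O(n^2)$ double-sum oracle.
* **Critical value $-1.65$** is a parameter, not a constant.
* **No pre-smoothing.** Some practitioners filter the series before
  testing; the analysis this package follows does not, so no filter is
  applied by default.

Degenerate inputs: a panel with zero cross-sectional variance anywhere
in the window (all units identical) has an undefined regressand and is a
hard "degenerate panel" error; a zero cross-sectional mean (only
possible for sign-mixed log panels) likewise errors rather than
returning nonsense ratios. A zero-residual fit (exactly collinear
construction) yields `se_gamma = 0`; the t-statistic is then reported as
signed infinity rather than NaN.

## Club identification

1. **Ordering.** Units are sorted by their final observation,
   descending; ties break alphabetically so results are reproducible.
   A `mean_last_half` alternative (mean over $t > T/2$) is provided
   because a single noisy final year can scramble the ordering, but the
   default follows the ordering rule of the analysis we implement.
2. **Core group.** For each starting position in that ordering, the
   log-t statistic is computed for the top-$R$ block, $R = 2,\dots$; the
   core is the block maximizing $t_\gamma$ among blocks with
   $t_\gamma > c^*$ ($c^* = -1.65$). We evaluate *all* $R$ rather than
   stopping at the first failure: the exhaustive scan is the literal
   reading of the selection rule and is cheap at realistic panel sizes.
3. **Sieve.** Each remaining unit joins if adding it alone to the core
   keeps $t_\gamma > c^*$. The extended club is then re-tested as a
   whole. The methodology is silent on what to do if that joint test
   fails; our rule raises $c^*$ stepwise (+0.5, with a floor at the
   smallest accepted t-statistic so the loop provably terminates) and
   re-sieves, shrinking the club until it passes — a reported club of
   size ≥ 2 therefore always passes the club-level test, which the
   partition constructor re-verifies.
4. **Recursion.** The leftover units are tested jointly; if they pass
   they form the last club, otherwise steps 1–3 repeat on them. A
   singleton remainder is always divergent (the test needs $N \ge 2$).

**Merging.** High $c^*$ protects against wrong members but fragments
true clubs. The merging pass tests each adjacent pair's union and merges
when the union passes, restarting the pass after every merge so chains
of fragments collapse transitively. Applying the pass to an already
merged partition is a no-op (idempotence, property-tested). The
divergent set is never touched by merging.

For a divergent set of size ≥ 2 we attach its log-t statistic *labelled
as diagnostic only*: a "divergence club" is not a convergence club, and
the statistic is reported for symmetry with published club tables, not
as a test result.

## The synthetic-data generator

`simulate_panel()` draws $e_{it}$ iid standard normal under the seed and
builds $X_{it} = \delta_{it}\mu_t$ with the loading law above. Choices:

* **$L(t)$ in the generator defaults to $\log(t+1)$.** The loading law
  with $L(t) = \log t$ divides by zero at $t = 1$; $\log(t+1)$ is the
  standard fix and keeps the first period stochastic. If the user
  insists on $L(t)=\log t$, the $t=1$ noise term is set to zero. The
  *test regression* is unaffected — it always uses the printed
  $L(t) = \log t$.
* **Common trend** $\mu_t = 1 + 0.02\,t$ by default: a deterministic
  2%-per-period growth path that keeps the panel positive and mimics
  slowly growing expenditure aggregates. A random-walk-with-drift
  option exists for realism; it is clamped away from zero because the
  transition machinery divides by the cross-sectional mean.
* **Divergent units** follow $\delta_{it} = \delta_i + b\,t/T$ plus the
  same decaying noise — a linear loading drift. The analysis we follow
  gives no explicit divergence law; a linear drift is the simplest
  process that never settles on any club's path.
* **Scale tag.** Generated panels default to `value_scale = "log"`,
  i.e. they *are* the analysis-scale series (the convergence stage of
  the motivating analysis runs on logs). `value_scale = "raw"`
  additionally enforces strict positivity and errors if a loading
  crosses zero.

What the generator emulates: the decay structure of the loading process
(club means, idiosyncratic scale $\theta$, speed $a$), planted club
partitions, divergent drifters, and the two-level variance structure of
the determinants stage. What it does **not** emulate: serial correlation
in $e_{it}$, cross-sectional dependence beyond the single common factor,
measurement revisions, or any calibration to real health-expenditure
series. A green recovery test therefore establishes algorithmic
correctness under the stated model, not performance on real data.

`simulate_rec_dataset()` plants a two-level linear model: covariates
standard normal on the modelling scale (read as logs of log-normal
indicators), grouping intercepts $N(0,\sigma_u^2)$, residuals
$N(0,\sigma_e^2)$, so the planted ICC is
$\sigma_u^2/(\sigma_u^2+\sigma_e^2)$.

## Composite indices

`pca_index()` eigendecomposes the correlation matrix (never the
covariance matrix — indicators arrive on wildly different scales).
Conventions: components sorted by eigenvalue; eigenvector signs fixed so
the first indicator loads non-negatively on every component (the
decomposition is sign-ambiguous and published tables print one arbitrary
choice); indicators with |loading| > 0.4 on component 1 flagged as
important contributors; component-1 scores computed from standardized
indicators when raw data are supplied. Missing rows are dropped casewise
before the correlation — no imputation happens inside the PCA.
`rescale_index(..., "shift_min_to_zero")` reproduces 0-anchored index
scales seen in summary tables; the exact published rescaling is
unstated, so only order-preserving affine maps are offered.

For any 2×2 correlation matrix the eigenvalues are exactly $1\pm\rho$
with loadings $\pm 1/\sqrt 2$ — asserted over a grid of $\rho$ as a
closed-form oracle — and the reconstruction
$V\Lambda V^{\top}$ must reproduce the correlation matrix to 1e-8.

## Within-grouping inequality

`gini()` uses the relative mean absolute difference
$G = \sum_{ij}|x_i-x_j|/(2n^2\bar x)$, computed via the $O(n\log n)$
sorted form and verified against the brute-force double sum. No
small-sample correction by default (the analysis names no formula); a
`corrected = TRUE` flag applies $n/(n-1)$. The coefficient is computed
on raw indicator levels — a Gini of logs is nonstandard — and a
log-scale panel triggers a warning, not an error. Properties tested:
scale invariance, population-replication invariance, Pigou–Dalton
(mean-preserving transfers strictly reduce $G$), and the log-normal
closed form $G = 2\Phi(\sigma/\sqrt 2)-1$.

`rec_gini_panel()` computes the grouping-year Gini and also emits the
country-level long layout in which each member country-year carries its
grouping's Gini — that replication is exactly the outcome structure the
mixed model consumes. The alternative reading (country-level indicator
as outcome) is available by passing any column as `outcome` to
`fit_mixed()` directly. Groupings with fewer than two members have no
within-grouping inequality and are excluded with a message.

## The determinants stage

`fit_mixed()` estimates the two-level random-intercept model by REML
(default; ML available for likelihood-ratio reporting) via lme4. Design
choices:

* **Robust standard errors.** Cluster-robust at the grouping level for
  the mixed and fixed-effects fits, HC1 for pooled OLS — the analysis
  says only "robust". For the mixed model the sandwich uses the
  closed-form inverse of the random-intercept marginal covariance
  $V_j = \sigma_e^2 I + \sigma_u^2 J$ (Sherman–Morrison), so no
  $n\times n$ solve occurs. With few groupings (8 in the motivating
  application) cluster-robust inference is approximate at best; the
  model-based SEs are one flag away (`robust = FALSE`).
* **Boundary fits.** $\hat\sigma_u^2 = 0$ is returned with a
  `boundary` flag, never as an exception; the ICC is then 0 and the
  fixed effects coincide with pooled OLS (asserted to 1e-6 in tests on
  a construction that provably lands on the boundary).
* **LR against OLS.** Both likelihoods are ML on the same frame; the
  null pins $\sigma_u^2$ to the boundary, so the p-value uses the 50:50
  $\chi^2_0{:}\chi^2_1$ mixture.
* **ICC as pre-check.** `run_determinants()` reports
  "multilevel structure not indicated" when the ICC falls below 0.05 —
  a conventional screening threshold, not a test.

One acceptance check deserves a note: "planted ICC 0.75 recovered
±0.05 at G = 30 × 20 × 20" is read as a *bias* check. At $G = 30$ the
Monte-Carlo sd of a single fit's ICC is itself ≈ 0.05 (the variance
component is estimated from 30 group draws), so the test averages the
ICC over six replicate fits at the stated design size rather than
betting one seed against a one-sigma band; the band and the design size
are unchanged.

## Missing data and transforms

The long-format reader demands a balanced panel and reports every
missing (unit, year) cell. `balance()` offers two policies: drop any
unit with a gap (default — conservative, matching an analysis that
simply dropped countries with too many missing values), or linearly
interpolate *interior* gaps of run length ≤ k (default 2), always
logged, never silent. Log transforms of non-positive values are a hard
error; an explicit `offset` applies $\log(x+\varepsilon)$ because silent
offsets corrupt cross-unit comparability (several service-coverage
indicators genuinely reach 0).

## Known limitations

* Clustering results depend on the ordering rule when clubs overlap
  heavily; the package exposes both published rules but arbitrates no
  further.
* The log-t test assumes a single common factor; panels driven by
  several factors can produce transition paths the model does not
  describe.
* Cluster-robust inference with < 10 groupings should be interpreted
  cautiously (see above).
* The Gini here is unweighted across countries; population-weighted
  variants are out of scope.
* No alternative convergence tests (beta/sigma convergence, unit-root
  panels) and no alternative club detectors are provided.

## Reproducibility

Both generators are deterministic under their seed (bit-identical
across processes). Every pipeline run writes a `manifest.json` echoing
the full configuration, the seed and package/R versions; the simulation
study derives per-replicate seeds from the base seed so the whole table
is reproducible from one integer.
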