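# Shared fixture builders. Everything is generated in code; no binary data.

# Two-unit panel engineered so the log-t regressand is exactly 2*log(t):
# X = 1 +/- d_t with d_t = 0.5/(t log t) for t >= 2, d_1 = 0.5, giving
# H_t = d_t^2 and a zero-residual fit with slope 2, intercept 0.
closed_form_pair <- function(T_len = 20) {
  t <- seq_len(T_len)
  d <- c(0.5, 0.5 / (t[-1] * log(t[-1])))
  X <- rbind(A = 1 + d, B = 1 - d)
  panel_series(X, value_scale = "log")
}

# A diverging pair with positive cross-sectional variance at t = 1.
diverging_pair <- function(T_len = 40) {
  X <- rbind(A = rep(1, T_len), B = 0.5 + seq_len(T_len))
  panel_series(X, value_scale = "log")
}

# Small raw panel with calendar years, as a long data.frame.
long_panel_df <- function(units = c("A", "B", "C"), years = 2000:2009,
                          seed = 42) {
  set.seed(seed)
  expand_df <- expand.grid(unit = units, year = years,
                           stringsAsFactors = FALSE)
  expand_df$value <- exp(rnorm(nrow(expand_df), mean = 2, sd = 0.3))
  expand_df[order(expand_df$unit, expand_df$year), ]
}

# Standard planted three-club generating process used across tests.
three_club_spec <- function(seed, T_len = 40, per_club = 5) {
  dgp_spec(delta = rep(c(1, 2, 4), each = per_club), T_len = T_len,
           theta = 0.05, a = 0.75, seed = seed)
}

# Load the governance / ICT correlation matrices shipped as fixtures.
fixture_cor <- function(name) {
  path <- system.file("extdata", name, package = "oopclubs")
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}

# Read a long data.frame through the same code path as read_panel().
read_panel_from_df <- function(df) {
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  write.csv(df, path, row.names = FALSE)
  read_panel(path)
}

# Independent brute-force Gini oracle: the raw pairwise definition.
gini_bruteforce <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(x[i] - x[j])
  s / (2 * n^2 * mean(x))
}
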