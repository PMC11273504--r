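# Shared fixtures and independent oracles used across test files.

tiny_groups <- function() {
  list(
    group_config("A", "1", 6, 300, 20, 1.3, 0.15, on_test_date = "2015-06-01"),
    group_config("B", "2", 6, 320, 25, 1.5, 0.20, on_test_date = "2015-06-01")
  )
}

tiny_config <- function(...) sim_config(tiny_groups(), ...)

zero_noise_config <- function(...) {
  sim_config(tiny_groups(), sigma_daily_intake = 0, sigma_weighing = 0, ...)
}

# default 186-heifer trial at seed 1, generated once per test run
.fixture_env <- new.env(parent = emptyenv())
default_trial <- function() {
  if (is.null(.fixture_env$trial)) {
    .fixture_env$trial <- generate_trial(default_sim_config(), seed = 1)
  }
  .fixture_env$trial
}
default_summary <- function() {
  if (is.null(.fixture_env$summary)) {
    tr <- default_trial()
    .fixture_env$summary <- growth_summary_table(tr$heifers, tr$weights,
                                                 tr$intake)
  }
  .fixture_env$summary
}

# explicit normal-equations OLS oracle: coefficients, SEs, R^2
ols_oracle <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  resid <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(resid^2) / df
  se <- sqrt(diag(s2 * solve(XtX)))
  r2 <- 1 - sum(resid^2) / sum((y - mean(y))^2)
  list(beta = as.vector(beta), se = se, r_squared = r2,
       residuals = as.vector(resid), s2 = s2, df = df)
}

# toy growth-summary table with hand-set values
toy_summary <- function(n = 6, seed = 42) {
  set.seed(seed)
  adg1 <- round(runif(n, 1.0, 1.8), 2)
  adg2 <- adg1 + round(runif(n, -0.05, 0.05), 3)
  mmwt1 <- round(runif(n, 60, 75), 2)
  mmwt2 <- mmwt1 + round(runif(n, -0.5, 0.5), 2)
  ubf <- round(runif(n, 4, 12), 1)
  data.frame(
    id = sprintf("T%02d", seq_len(n)), group = rep("all", n),
    initial_bw = round(runif(n, 270, 330), 1),
    final_bw = round(runif(n, 360, 440), 1),
    adg1 = adg1, adg2 = adg2, mmwt1 = mmwt1, mmwt2 = mmwt2,
    mean_dmi = round(2 + 1.5 * adg1 + 0.09 * mmwt1 + rnorm(n, 0, 0.6), 3),
    days = 70, ubf_mm = ubf, stringsAsFactors = FALSE
  )
}
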