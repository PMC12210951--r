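# Shared test helpers: published coefficient CIs and small synthetic builders.

# 95% CIs printed for the growth fit
growth_ci_published <- list(
  a = c(0.0299, 0.06555),
  b = c(2.039, 2.172),
  c = c(0.6247, 0.7412),
  d = c(7.532, 7.632))

# 95% CIs printed for the substrate fit (free coefficients)
substrate_ci_published <- list(
  s0 = c(30.12, 30.76),
  b = c(2.41, 5.424),
  M = c(1.362, 2.353),
  N = c(0.01189, 0.1732))

# noise-free growth series from known parameters
make_growth_series <- function(params = c(a = 0.05, b = 2.2, c = 0.6, d = 7.5),
                               times = seq(0, 14, by = 2)) {
  ferm_series(times, eval_growth(times, params),
              lactate = rep(0, length(times)) + seq_along(times) * 0.1,
              glucose_consumed = seq_along(times) * 0.1)
}

# brute-force SSE minimum over a parameter grid (independent NLS oracle)
grid_min_sse <- function(t, y, model_fun, grids) {
  g <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  min(apply(g, 1, function(row) sum((model_fun(t, row) - y)^2)))
}

expect_within_ci <- function(value, ci) {
  expect_gte(value, ci[1])
  expect_lte(value, ci[2])
}
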