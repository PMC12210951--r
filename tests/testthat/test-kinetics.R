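paper_growth <- c(a = 0.04773, b = 2.106, c = 0.683, d = 7.582)
paper_product <- c(p0 = 0, m = 1.559, n = 0.07135, a = 0.04772, b = 4.821,
                   c = 0.683)
paper_substrate <- c(s0 = 30.44, M = 1.858, N = 0.09254, a = 0.0477,
                     b = 3.917, c = 0.683)

test_that("closed forms obey their boundary identities", {
  expect_equal(eval_growth(0, paper_growth),
               paper_growth[["a"]] + paper_growth[["d"]])
  # logistic asymptote: increment saturates at b
  expect_equal(eval_growth(1e3, paper_growth),
               paper_growth[["b"]] + paper_growth[["d"]], tolerance = 1e-9)
  expect_equal(eval_product(0, paper_product),
               paper_product[["p0"]] + paper_product[["m"]] * paper_product[["a"]])
  expect_equal(eval_substrate(0, paper_substrate),
               paper_substrate[["s0"]] - paper_substrate[["M"]] * paper_substrate[["a"]])
  # degenerate coefficients give constant curves
  pconst <- paper_product; pconst[c("m", "n")] <- 0; pconst["p0"] <- 3
  expect_equal(eval_product(c(0, 5, 14), pconst), rep(3, 3))
  sconst <- paper_substrate; sconst[c("M", "N")] <- 0
  expect_equal(eval_substrate(c(0, 5, 14), sconst), rep(30.44, 3))
})

test_that("closed forms at 14 h match the observed batch-culture values", {
  t3 <- load_builtin("table3")
  obs14 <- t3[t3$time == 14, ]
  expect_lt(abs(eval_growth(14, paper_growth) - obs14$viable_lg), 0.05)
  expect_lt(abs(eval_product(14, paper_product) - obs14$lactate), 0.2)
  consumed14 <- paper_substrate[["s0"]] - eval_substrate(14, paper_substrate)
  expect_lt(abs(consumed14 - obs14$glucose_consumed), 0.2)
})

test_that("growth curve is monotone non-decreasing and bounded by b + d", {
  tt <- seq(0, 14, by = 0.1)
  x <- eval_growth(tt, paper_growth)
  expect_true(all(diff(x) >= 0))
  expect_true(all(x <= paper_growth[["b"]] + paper_growth[["d"]] + 1e-12))
})

test_that("closed forms agree with numeric integration of the ODEs", {
  skip_if_not_installed("deSolve")
  tt <- seq(0, 14, by = 0.5)
  # growth
  out <- deSolve::ode(
    y = c(x = paper_growth[["a"]]), times = tt,
    func = function(t, y, p) list(ode_rhs("growth", y, t, paper_growth)),
    rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(out[, "x"] -
                      (eval_growth(tt, paper_growth) - paper_growth[["d"]]))),
            1e-6)
  # product (coupled with its own logistic increment)
  out <- deSolve::ode(
    y = c(x = paper_product[["a"]], p = eval_product(0, paper_product)),
    times = tt,
    func = function(t, y, p) list(ode_rhs("product", y, t, paper_product)),
    rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(out[, "p"] - eval_product(tt, paper_product))), 1e-6)
  # substrate
  out <- deSolve::ode(
    y = c(x = paper_substrate[["a"]], s = eval_substrate(0, paper_substrate)),
    times = tt,
    func = function(t, y, p) list(ode_rhs("substrate", y, t, paper_substrate)),
    rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(out[, "s"] - eval_substrate(tt, paper_substrate))), 1e-6)
})

test_that("ode_rhs vanishes at the fixed points", {
  expect_equal(unname(ode_rhs("growth", c(x = paper_growth[["b"]]), 0,
                              paper_growth)), 0)
  expect_equal(unname(ode_rhs("product", c(x = 0, p = 1), 0, paper_product)),
               c(0, 0))
})

test_that("noise-free synthetic growth data are recovered exactly", {
  truth <- c(a = 0.05, b = 2.2, c = 0.6, d = 7.5)
  series <- make_growth_series(truth)
  cons <- kin_constraints(names(truth), start = unname(truth),
                          lower = rep(0, 4), upper = rep(Inf, 4))
  fit <- fit_growth(series, cons)
  expect_true(fit$converged)
  expect_equal(coef(fit), truth, tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_lt(fit$rmse, 1e-8)
})

test_that("NLS solution beats a brute-force parameter-grid oracle", {
  truth <- c(a = 0.06, b = 2.0, c = 0.65, d = 7.4)
  tt <- c(0, 3, 6, 9, 12)
  set.seed(11)
  y <- eval_growth(tt, truth) + rnorm(5, sd = 0.01)
  series <- ferm_series(tt, y, rep(0.1, 5), rep(0.1, 5))
  fit <- fit_growth(series)
  oracle <- grid_min_sse(
    tt, y,
    function(t, p) eval_growth(t, c(a = p[[1]], b = p[[2]], c = p[[3]],
                                    d = p[[4]])),
    list(a = seq(0.02, 0.12, length.out = 8),
         b = seq(1.5, 2.5, length.out = 8),
         c = seq(0.4, 0.9, length.out = 8),
         d = seq(7.2, 7.6, length.out = 8)))
  expect_lte(fit$sse, oracle + 1e-12)
})

test_that("product fit holds a and c fixed and beats a grid oracle", {
  gf <- fit_growth(load_builtin("table3"))
  pf <- fit_product(load_builtin("table3"), growth_fit = gf)
  expect_false(pf$free[["a"]])
  expect_false(pf$free[["c"]])
  expect_equal(pf$dfe, 4)  # 8 points, 4 free coefficients
  expect_equal(pf$params[["a"]], 0.0477)
  expect_equal(pf$params[["c"]], 0.683)

  # grid oracle on a small synthetic product data set
  truth <- c(p0 = 0.2, m = 1.4, n = 0.06, a = 0.0477, b = 4, c = 0.683)
  tt <- seq(0, 12, by = 2)  # 7 points is comfortably above the 4 free params
  set.seed(5)
  y <- eval_product(tt, truth) + rnorm(7, sd = 0.05)
  series <- ferm_series(tt, rep(8, 7), pmax(y, 0), seq(0, 6, length.out = 7))
  fit <- fit_product(series)
  oracle <- grid_min_sse(
    tt, pmax(y, 0),
    function(t, p) eval_product(t, c(p0 = p[[1]], m = p[[2]], n = p[[3]],
                                     a = 0.0477, b = p[[4]], c = 0.683)),
    list(p0 = seq(0, 0.5, length.out = 6),
         m = seq(1, 2, length.out = 6),
         n = seq(0.02, 0.12, length.out = 6),
         b = seq(3, 6, length.out = 6)))
  expect_lte(fit$sse, oracle + 1e-12)
})

test_that("substrate fit outputs are invariant to the reconstruction offset", {
  t3 <- load_builtin("table3")
  f1 <- fit_substrate(t3, K = 30.44)
  f2 <- fit_substrate(t3, K = 50)
  expect_equal(f2$params[["s0"]] - f1$params[["s0"]], 50 - 30.44,
               tolerance = 1e-6)
  # exact in theory; the solver path diverges at floating-point level
  for (nm in c("M", "N", "b"))
    expect_equal(f2$params[[nm]], f1$params[[nm]], tolerance = 1e-6)
  expect_equal(f2$r_squared, f1$r_squared, tolerance = 1e-8)
  expect_equal(f2$rmse, f1$rmse, tolerance = 1e-6)
})

test_that("gof metrics follow their definitions", {
  y <- c(1, 2, 3, 4, 5, 6)
  m <- gof_metrics(y, y, 2)
  expect_equal(m$r_squared, 1)
  expect_equal(m$rmse, 0)
  m2 <- gof_metrics(y, rep(mean(y), 6), 2)
  expect_equal(m2$r_squared, 0)
  expect_error(gof_metrics(rep(1, 5), rep(1, 5), 2), "undefined")
  expect_error(gof_metrics(y, y, 6), "observations")

  # published growth coefficients reproduce the printed RMSE under dfe = n - p
  t3 <- load_builtin("table3")
  m3 <- gof_metrics(t3$viable_lg, eval_growth(t3$time, paper_growth), 4)
  expect_equal(m3$rmse, 0.0156, tolerance = 1e-2)
})

test_that("confidence intervals behave as Wald intervals should", {
  gf <- fit_growth(load_builtin("table3"))
  ci <- confidence_intervals(gf)
  c_row <- ci[ci$coef == "c", ]
  # overlaps the published interval
  expect_lt(c_row$lower, 0.7412)
  expect_gt(c_row$upper, 0.6247)

  # zero-noise fit: interval width collapses
  series <- make_growth_series()
  fit0 <- fit_growth(series, kin_constraints(
    c("a", "b", "c", "d"), start = c(0.05, 2.2, 0.6, 7.5),
    lower = rep(0, 4), upper = rep(Inf, 4)))
  ci0 <- confidence_intervals(fit0)
  expect_lt(max(ci0$upper - ci0$lower), 1e-5)

  # width is monotone in the level
  ci95 <- confidence_intervals(gf, 0.95)
  ci68 <- confidence_intervals(gf, 0.68)
  expect_true(all(ci95$upper - ci95$lower >= ci68$upper - ci68$lower))

  # fixed coefficients get degenerate intervals
  pf <- fit_product(load_builtin("table3"))
  cip <- confidence_intervals(pf)
  expect_equal(cip$lower[cip$coef == "a"], cip$upper[cip$coef == "a"])
})

test_that("degenerate inputs are rejected with explicit errors", {
  short <- ferm_series(c(0, 2, 4), c(7.6, 7.8, 8.2), c(0, 1, 2), c(0, 1, 2))
  expect_error(fit_growth(short), "at least")
  expect_error(eval_growth(1, c(a = 2, b = 1, c = 0.5, d = 0)), "invalid")
})
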