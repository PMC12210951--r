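test_that("min-max scaler maps to [-1, 1] and round-trips", {
  X <- cbind(a = c(10, 20, 30), b = c(1, 5, 9))
  sc <- fit_scaler(X)
  Xs <- scale_apply(sc, X)
  expect_equal(unname(Xs[, 1]), c(-1, 0, 1))
  expect_equal(scale_unapply(sc, Xs), unname(X), ignore_attr = TRUE,
               tolerance = 1e-12)
  # extrapolation is permitted: 40 on a (10, 30) feature maps to 2
  expect_equal(scale_apply(sc, c(40, 5))[1, 1], 2)
  expect_error(fit_scaler(cbind(c(1, 1, 1), c(1, 2, 3))), "constant feature")
})

test_that("forward pass matches pencil-and-paper arithmetic", {
  # 1-2-1 toy net evaluated by hand
  net <- structure(list(W1 = matrix(c(0.5, -1), 2, 1), b1 = c(0.1, 0.2),
                        w2 = c(2, -3), b2 = 0.25, n_in = 1L, n_hidden = 2L),
                   class = "mlp")
  x <- 0.4
  manual <- 2 * tanh(0.5 * x + 0.1) - 3 * tanh(-1 * x + 0.2) + 0.25
  expect_equal(mlp_forward(net, x), manual, tolerance = 1e-12)

  # all-zero weights return the output bias
  net0 <- net; net0$W1[] <- 0; net0$b1[] <- 0; net0$w2[] <- 0
  expect_equal(mlp_forward(net0, 0.7), 0.25)

  # invariance under permuting hidden units with their weights
  netp <- net
  netp$W1 <- net$W1[2:1, , drop = FALSE]; netp$b1 <- net$b1[2:1]
  netp$w2 <- net$w2[2:1]
  expect_equal(mlp_forward(netp, x), mlp_forward(net, x), tolerance = 1e-14)

  expect_error(mlp_forward(net, c(1, 2)), "features")
})

test_that("regression metrics follow their definitions", {
  expect_equal(regression_metrics(c(1, 2, 3), c(1, 2, 3)),
               list(rmse = 0, r_squared = 1, mae = 0))
  m <- regression_metrics(c(0, 2), c(1, 1))
  expect_equal(m$rmse, 1)
  expect_equal(m$mae, 1)
  expect_equal(m$r_squared, 0)
  # MAE <= RMSE (Jensen) on random cases
  set.seed(2)
  for (i in 1:10) {
    y <- rnorm(20); yh <- y + rnorm(20)
    mm <- regression_metrics(y, yh)
    expect_lte(mm$mae, mm$rmse + 1e-12)
  }
  expect_error(regression_metrics(rep(1, 4), c(1, 1, 1, 2)), "zero variance")
})

test_that("training is deterministic and fits a representable target", {
  set.seed(7)
  X <- matrix(runif(60, -1, 1), 20, 3)
  y <- X[, 1]  # noise-free linear target
  t1 <- train_bayesian_lm(X, y, seed = 3)
  t2 <- train_bayesian_lm(X, y, seed = 3)
  expect_identical(t1$net, t2$net)  # bit-for-bit reproducibility
  expect_lt(regression_metrics(y, mlp_forward(t1$net, X))$rmse, 1e-3)
})

test_that("training keeps its evidence-framework invariants", {
  set.seed(9)
  X <- matrix(runif(60, -1, 1), 20, 3)
  y <- 0.5 * X[, 1] - 0.3 * X[, 2]^2 + 0.1
  tr <- train_bayesian_lm(X, y, seed = 1)
  st <- tr$state
  # every accepted LM step decreased the objective in force at that step
  expect_true(all(st$step_drop > 0))
  # effective parameter count stays within [0, weight count]
  expect_true(all(st$gamma_history >= 0 & st$gamma_history <= st$n_weights))
  expect_gt(st$alpha, 0)
  expect_gt(st$beta, 0)
})

test_that("the surrogate learns a noise-free quadratic response surface", {
  d <- box_behnken(list(x1 = c(-1, 0, 1), x2 = c(-1, 0, 1), x3 = c(-1, 0, 1)))
  surf <- quad_surface()
  r2 <- vapply(0:4, function(s) {
    sim <- simulate_bbd(d, surf, noise_sd = 0, seed = s)
    coded <- as.matrix(sim[, grep("_coded$", names(sim))])
    sur <- suppressWarnings(fit_surrogate(coded, sim$response, n_hidden = 8,
                                          decay = 0.01, n_starts = 3,
                                          seed = s, max_epochs = 400))
    sur$metrics$r_squared
  }, numeric(1))
  expect_gte(median(r2), 0.95)
})

test_that("k-fold cross-validation machinery is sound", {
  set.seed(1)
  X6 <- matrix(runif(18, -1, 1), 6, 3)
  y6 <- X6[, 1] + rnorm(6, 0, 0.01)
  # leave-one-out runs without error (fold R2 undefined -> NA)
  cv6 <- suppressWarnings(kfold_cv(X6, y6, k = 6, seed = 1, max_epochs = 50))
  expect_equal(nrow(cv6), 6)
  expect_true(all(is.na(cv6$r2_test)))

  set.seed(2)
  X <- matrix(runif(60, -1, 1), 20, 3)
  y <- 0.8 * X[, 1] + rnorm(20, 0, 0.05)
  cv <- kfold_cv(X, y, k = 5, seed = 2, max_epochs = 100)
  expect_equal(nrow(cv), 5)
  # reported means are the arithmetic fold means
  expect_equal(attr(cv, "means")[["mae_test"]], mean(cv$mae_test),
               tolerance = 1e-12)
  expect_error(kfold_cv(X6, y6, k = 7), "exceed")
})

test_that("cross-validated surrogate generalizes on an informative design", {
  surf <- quad_surface()
  q2 <- vapply(1:3, function(s) {
    set.seed(s + 100)
    X <- matrix(runif(135, -1, 1), 45, 3)
    y <- apply(X, 1, surf$value) + rnorm(45, 0, 0.01)
    cv <- suppressWarnings(kfold_cv(X, y, k = 5, seed = s, n_hidden = 8,
                                    decay = 0.01, max_epochs = 300))
    attr(cv, "pooled")$q2
  }, numeric(1))
  expect_gte(median(q2), 0.85)
})
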