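#' Fit a min-max scaler to [-1, 1]
#'
#' Records per-feature minima and maxima so that the fitting set spans
#' exactly \[-1, 1\] after [scale_apply()]. Out-of-range values extrapolate
#' linearly.
#'
#' @param X Numeric matrix or data frame (rows = observations).
#' @return List of class `minmax_scaler` with `min` and `max` per feature.
#' @export
fit_scaler <- function(X) {
  X <- as.matrix(X)
  mn <- apply(X, 2, min)
  mx <- apply(X, 2, max)
  const <- which(mx - mn <= 0)
  if (length(const))
    stop("constant feature(s) cannot be scaled: ",
         paste(colnames(X)[const] %||% const, collapse = ", "))
  structure(list(min = mn, max = mx), class = "minmax_scaler")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply / invert a min-max scaler
#'
#' @param scaler A `minmax_scaler`.
#' @param X Matrix (or vector, treated as one row) on the original scale for
#'   `scale_apply`, or on the \[-1, 1\] scale for `scale_unapply`.
#' @return Matrix of the same shape on the other scale.
#' @export
scale_apply <- function(scaler, X) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  sweep(sweep(X, 2, scaler$min), 2, scaler$max - scaler$min, "/") * 2 - 1
}

#' @rdname scale_apply
#' @export
scale_unapply <- function(scaler, X) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  sweep(sweep((X + 1) / 2, 2, scaler$max - scaler$min, "*"), 2, scaler$min, "+")
}

#' Create a single-hidden-layer perceptron
#'
#' Feed-forward network with hyperbolic-tangent hidden units and a linear
#' output: y = w2 . tanh(W1 x + b1) + b2. Weights are drawn from a seeded
#' uniform distribution on \[-0.5, 0.5\].
#'
#' @param n_in,n_hidden Input and hidden layer sizes (default 3 and 3).
#' @param seed Integer seed for the weight initialization.
#' @return List of class `mlp` with `W1` (hidden x in), `b1`, `w2`, `b2`.
#' @export
mlp_init <- function(n_in = 3L, n_hidden = 3L, seed = 1L) {
  set.seed(seed)
  k <- n_hidden * n_in + n_hidden + n_hidden + 1L
  w <- stats::runif(k, -0.5, 0.5)
  .mlp_from_weights(w, n_in, n_hidden)
}

.mlp_from_weights <- function(w, n_in, n_hidden) {
  i <- 0L
  W1 <- matrix(w[i + seq_len(n_hidden * n_in)], n_hidden, n_in)
  i <- i + n_hidden * n_in
  b1 <- w[i + seq_len(n_hidden)]; i <- i + n_hidden
  w2 <- w[i + seq_len(n_hidden)]; i <- i + n_hidden
  b2 <- w[i + 1L]
  structure(list(W1 = W1, b1 = b1, w2 = w2, b2 = b2,
                 n_in = n_in, n_hidden = n_hidden),
            class = "mlp")
}

.mlp_weights <- function(net) c(as.vector(net$W1), net$b1, net$w2, net$b2)

#' Forward pass of the perceptron
#'
#' @param net An `mlp`.
#' @param X Matrix of scaled inputs (rows = observations) or a single vector.
#' @return Numeric vector of predictions, one per row.
#' @export
mlp_forward <- function(net, X) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1) else as.matrix(X)
  if (ncol(X) != net$n_in)
    stop("input has ", ncol(X), " features; network expects ", net$n_in)
  H <- tanh(X %*% t(net$W1) + matrix(net$b1, nrow(X), net$n_hidden, byrow = TRUE))
  as.vector(H %*% net$w2 + net$b2)
}

# Jacobian of predictions w.r.t. the weight vector, analytic.
.mlp_jacobian <- function(net, X) {
  n <- nrow(X); h <- net$n_hidden
  Z <- X %*% t(net$W1) + matrix(net$b1, n, h, byrow = TRUE)
  Hc <- tanh(Z)
  dH <- 1 - Hc^2                                 # n x h
  Jw1 <- matrix(0, n, h * net$n_in)
  for (j in seq_len(h))
    for (k in seq_len(net$n_in))
      Jw1[, (k - 1) * h + j] <- net$w2[j] * dH[, j] * X[, k]
  Jb1 <- sweep(dH, 2, net$w2, "*")
  cbind(Jw1, Jb1, Hc, 1)
}

#' Train the perceptron by Bayesian-regularized Levenberg-Marquardt
#'
#' Minimizes the evidence-framework objective F = beta SSE + alpha SSW
#' (SSW = sum of squared weights) by damped Gauss-Newton steps. After each
#' accepted step the hyperparameters are re-estimated by the MacKay updates:
#' gamma = k - 2 alpha tr(H^-1) with H = 2 beta J'J + 2 alpha I,
#' alpha = gamma / (2 SSW), beta = (n - gamma) / (2 SSE). Training stops at
#' `max_epochs`, when the damping factor overflows, or when the gradient
#' infinity-norm drops below `gtol`. Inputs and target are expected already
#' scaled (see [fit_scaler()]); training is deterministic given `seed`.
#'
#' @param X Matrix of scaled inputs.
#' @param y Scaled target vector.
#' @param n_hidden Hidden units, default 3.
#' @param seed Seed for weight initialization.
#' @param max_epochs Maximum LM epochs, default 200.
#' @param gtol Gradient tolerance, default 1e-10.
#' @param mu0,mu_max Initial and maximal damping, defaults 0.005 and 1e10.
#' @param burn_in Number of initial epochs trained with the hyperparameters
#'   frozen (alpha small, beta = 1) before the evidence updates start,
#'   default 25. Updating from a cold start can over-regularize: with the
#'   weights still near their random initialization the update
#'   alpha = gamma/(2 SSW) is large, shrinking the weights further in a
#'   feedback loop that ends at the constant predictor. Letting the data
#'   term dominate until the residuals are informative avoids that
#'   degenerate fixed point.
#' @param decay If non-NULL, train with a fixed weight-decay ratio instead
#'   of the evidence updates: alpha = `decay`, beta = 1 throughout. The
#'   evidence updates assume more observations than well-determined
#'   parameters; when n is close to (or below) the weight count they are
#'   ill-posed, and a fixed small decay gives the smooth minimum-norm
#'   behaviour the surrogate needs.
#' @return List with `net` (the trained `mlp`) and `state` (class
#'   `br_train_state`: final alpha, beta, gamma, mu, epochs, per-epoch
#'   objective history and the termination reason).
#' @export
train_bayesian_lm <- function(X, y, n_hidden = 3L, seed = 1L,
                              max_epochs = 200L, gtol = 1e-10,
                              mu0 = 0.005, mu_max = 1e10, burn_in = 25L,
                              decay = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (length(y) != n) stop("X and y disagree on the number of observations")
  if (any(!is.finite(X)) || any(!is.finite(y))) stop("non-finite training data")
  net <- mlp_init(ncol(X), n_hidden, seed)
  w <- .mlp_weights(net)
  k <- length(w)
  if (n < k / 3)
    warning("only ", n, " observations for ", k,
            " weights; the surrogate may be under-determined")
  fixed_ratio <- !is.null(decay)
  alpha <- if (fixed_ratio) decay else 0.01
  beta <- 1; mu <- mu0
  if (fixed_ratio) burn_in <- Inf  # hyperparameters stay frozen
  objective <- function(w) {
    netw <- .mlp_from_weights(w, ncol(X), n_hidden)
    r <- mlp_forward(netw, X) - y
    list(net = netw, r = r, sse = sum(r^2), ssw = sum(w^2))
  }
  cur <- objective(w)
  Fcur <- beta * cur$sse + alpha * cur$ssw
  history <- numeric(0)
  gamma_history <- numeric(0)
  step_drop <- numeric(0)  # F decrease of each accepted step at fixed alpha/beta
  reason <- "max_epochs"
  epoch <- 0L
  accepted_drop <- logical(0)
  while (epoch < max_epochs) {
    epoch <- epoch + 1L
    J <- .mlp_jacobian(cur$net, X)
    g <- 2 * (beta * crossprod(J, cur$r) + alpha * w)
    if (max(abs(g)) < gtol) { reason <- "gradient"; break }
    A <- 2 * (beta * crossprod(J) + alpha * diag(k))
    repeat {
      step <- tryCatch(solve(A + mu * diag(k), -g), error = function(e) NULL)
      cand <- if (!is.null(step)) objective(w + as.vector(step))
      Fcand <- if (!is.null(step)) beta * cand$sse + alpha * cand$ssw else Inf
      if (is.finite(Fcand) && Fcand < Fcur) {
        accepted_drop <- c(accepted_drop, TRUE)
        step_drop <- c(step_drop, Fcur - Fcand)
        w <- w + as.vector(step)
        cur <- cand
        mu <- max(mu / 10, 1e-20)
        break
      }
      mu <- mu * 10
      if (mu > mu_max) break
    }
    if (mu > mu_max) { reason <- "mu_overflow"; break }
    # MacKay evidence updates at the new point (after burn-in)
    Hinv <- if (epoch > burn_in)
      tryCatch(solve(2 * (beta * crossprod(.mlp_jacobian(cur$net, X)) +
                            alpha * diag(k))),
               error = function(e) NULL)
    if (!is.null(Hinv)) {
      gamma <- k - 2 * alpha * sum(diag(Hinv))
      gamma <- min(max(gamma, 0), k)
      if (cur$ssw > 0) alpha <- max(gamma / (2 * cur$ssw), 1e-12)
      if (cur$sse > 0 && n > gamma) beta <- max((n - gamma) / (2 * cur$sse), 1e-12)
      gamma_history <- c(gamma_history, gamma)
    }
    Fcur <- beta * cur$sse + alpha * cur$ssw
    history <- c(history, Fcur)
  }
  gamma <- if (exists("gamma", inherits = FALSE)) gamma else NA_real_
  state <- structure(list(alpha = alpha, beta = beta, gamma = gamma, mu = mu,
                          epochs = epoch, objective_history = history,
                          gamma_history = gamma_history,
                          step_drop = step_drop,
                          n_weights = k,
                          accepted_steps = sum(accepted_drop),
                          sse = cur$sse, ssw = cur$ssw, reason = reason),
                     class = "br_train_state")
  list(net = cur$net, state = state)
}

#' Regression metrics
#'
#' RMSE = sqrt(mean squared error), MAE = mean absolute error,
#' R-squared = 1 - SSE/SST about the mean of `y`.
#'
#' @param y Observed values.
#' @param yhat Predictions.
#' @return List with `rmse`, `r_squared`, `mae`.
#' @export
regression_metrics <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat lengths differ")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("zero variance in y: R-squared is undefined")
  e <- y - yhat
  list(rmse = sqrt(mean(e^2)), r_squared = 1 - sum(e^2) / sst,
       mae = mean(abs(e)))
}

#' K-fold cross-validation of the Bayesian-regularized surrogate
#'
#' Seeded shuffle into `k` near-equal folds; each fold is held out once while
#' a network is trained on the rest with identical configuration. Metrics are
#' computed in the scaled space for both the training and the held-out
#' partition of every fold. The scaler is refit on each training partition.
#'
#' @param X Matrix of raw (unscaled) inputs.
#' @param y Raw target vector.
#' @param k Number of folds, default 5.
#' @param seed Seed controlling the shuffle and weight initializations.
#' @param n_hidden Hidden units, default 3.
#' @param max_epochs LM epochs per fold, default 200.
#' @param decay Optional fixed weight-decay ratio passed to
#'   [train_bayesian_lm()].
#' @return Data frame of class `cv_report`: per-fold `rmse_train`,
#'   `r2_train`, `mae_train`, `rmse_test`, `r2_test`, `mae_test` (fold R2 is
#'   NA when a fold holds fewer than 2 points); attribute `means` holds
#'   their arithmetic means and attribute `pooled` the raw-scale RMSE, MAE
#'   and Q2 (R2 of all pooled held-out predictions about the overall mean),
#'   which is the stable generalization summary for small designs.
#' @export
kfold_cv <- function(X, y, k = 5L, seed = 1L, n_hidden = 3L,
                     max_epochs = 200L, decay = NULL) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (k > n) stop("k = ", k, " folds exceed n = ", n, " observations")
  if (k < 2) stop("need at least 2 folds")
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  pooled_pred <- numeric(n)
  rows <- lapply(seq_len(k), function(i) {
    tr <- fold != i
    sx <- fit_scaler(X[tr, , drop = FALSE])
    sy <- fit_scaler(matrix(y[tr], ncol = 1))
    Xtr <- scale_apply(sx, X[tr, , drop = FALSE])
    ytr <- as.vector(scale_apply(sy, matrix(y[tr], ncol = 1)))
    trained <- train_bayesian_lm(Xtr, ytr, n_hidden = n_hidden,
                                 seed = seed + i, max_epochs = max_epochs,
                                 decay = decay)
    mtr <- regression_metrics(ytr, mlp_forward(trained$net, Xtr))
    Xte <- scale_apply(sx, X[!tr, , drop = FALSE])
    yte <- as.vector(scale_apply(sy, matrix(y[!tr], ncol = 1)))
    pte <- mlp_forward(trained$net, Xte)
    pooled_pred[!tr] <<- as.vector(scale_unapply(sy, matrix(pte, ncol = 1)))
    e <- yte - pte
    r2_te <- if (length(yte) >= 2 && stats::var(yte) > 0)
      1 - sum(e^2) / sum((yte - mean(yte))^2) else NA_real_
    data.frame(fold = i,
               rmse_train = mtr$rmse, r2_train = mtr$r_squared,
               mae_train = mtr$mae,
               rmse_test = sqrt(mean(e^2)), r2_test = r2_te,
               mae_test = mean(abs(e)))
  })
  out <- do.call(rbind, rows)
  attr(out, "means") <- colMeans(out[, -1], na.rm = TRUE)
  e_raw <- y - pooled_pred
  attr(out, "pooled") <- list(
    rmse = sqrt(mean(e_raw^2)), mae = mean(abs(e_raw)),
    q2 = 1 - sum(e_raw^2) / sum((y - mean(y))^2))
  class(out) <- c("cv_report", "data.frame")
  out
}

#' Train a surrogate end-to-end on raw design data
#'
#' Convenience wrapper: fits input and target scalers, trains the network in
#' the scaled space, and returns a predictor on the original units.
#'
#' @inheritParams train_bayesian_lm
#' @param X Raw design matrix (e.g. decoded Box-Behnken runs).
#' @param y Raw responses (e.g. viable counts, lg CFU/mL).
#' @param n_starts Number of seeded weight initializations; the restart with
#'   the lowest final regularized objective is kept (default 1).
#' @return List of class `surrogate`: `net`, `state`, `scaler_x`, `scaler_y`,
#'   `predict(newX)` returning raw-scale predictions, and training `metrics`
#'   (scaled space).
#' @export
fit_surrogate <- function(X, y, n_hidden = 3L, seed = 1L, max_epochs = 200L,
                          decay = NULL, n_starts = 1L) {
  X <- as.matrix(X); y <- as.numeric(y)
  sx <- fit_scaler(X)
  sy <- fit_scaler(matrix(y, ncol = 1))
  Xs <- scale_apply(sx, X)
  ys <- as.vector(scale_apply(sy, matrix(y, ncol = 1)))
  trained <- NULL
  for (st in seq_len(max(1L, n_starts))) {
    cand <- train_bayesian_lm(Xs, ys, n_hidden = n_hidden,
                              seed = (seed %% 1000003L) * 1000L + st - 1L,
                              max_epochs = max_epochs, decay = decay)
    Fcand <- cand$state$beta * cand$state$sse + cand$state$alpha * cand$state$ssw
    if (is.null(trained) || Fcand < trained$Fbest) {
      trained <- cand
      trained$Fbest <- Fcand
    }
  }
  predict_fun <- function(newX) {
    p <- mlp_forward(trained$net, scale_apply(sx, newX))
    as.vector(scale_unapply(sy, matrix(p, ncol = 1)))
  }
  structure(list(net = trained$net, state = trained$state,
                 scaler_x = sx, scaler_y = sy, predict = predict_fun,
                 metrics = regression_metrics(ys, mlp_forward(trained$net, Xs))),
            class = "surrogate")
}
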