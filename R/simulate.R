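#' Default ground-truth kinetic parameters for simulation
#'
#' The fitted batch-culture coefficients of the study system, used as the
#' generator's ground truth: growth (a, b, c, d), product (p0, m, n sharing
#' a, b, c of the product fit) and substrate (s0, M, N sharing a, b, c of
#' the substrate fit).
#'
#' @return Named list with `growth`, `product`, `substrate` parameter vectors.
#' @export
default_sim_params <- function() {
  list(
    growth = c(a = 0.04773, b = 2.106, c = 0.683, d = 7.582),
    product = c(p0 = 0, m = 1.559, n = 0.07135, a = 0.04772, b = 4.821, c = 0.683),
    substrate = c(s0 = 30.44, M = 1.858, N = 0.09254, a = 0.0477, b = 3.917, c = 0.683))
}

#' Simulate a batch fermentation time series
#'
#' Noise-free channels follow the closed-form growth, product and substrate
#' curves exactly; independent additive Gaussian noise is then applied per
#' observation and channel. The substrate channel is reported as cumulative
#' glucose consumed (s0 minus the residual-substrate curve), matching the
#' observed-data convention.
#'
#' @param params List with `growth`, `product`, `substrate` parameter vectors
#'   (see [default_sim_params()]).
#' @param times Sampling times, hours; default 0 to 14 by 2 (the study grid).
#' @param noise_sd Named vector of Gaussian noise standard deviations for
#'   `viable_lg`, `lactate`, `glucose_consumed`; default c(0.02, 0.15, 0.15).
#' @param seed Integer seed; all randomness flows from it.
#' @return A `ferm_series`.
#' @export
simulate_fermentation <- function(params = default_sim_params(),
                                  times = seq(0, 14, by = 2),
                                  noise_sd = c(viable_lg = 0.02,
                                               lactate = 0.15,
                                               glucose_consumed = 0.15),
                                  seed = 1L) {
  stopifnot(all(noise_sd >= 0))
  x <- eval_growth(times, params$growth)
  p <- eval_product(times, params$product)
  s_resid <- eval_substrate(times, params$substrate)
  consumed <- params$substrate[["s0"]] - s_resid
  set.seed(seed)
  n <- length(times)
  x <- x + stats::rnorm(n, sd = noise_sd[["viable_lg"]])
  p <- pmax(p + stats::rnorm(n, sd = noise_sd[["lactate"]]), 0)
  consumed <- pmax(consumed + stats::rnorm(n, sd = noise_sd[["glucose_consumed"]]), 0)
  p[1] <- max(p[1], 0)
  ferm_series(times, pmax(x, 1e-6), p, consumed)
}

#' Define a quadratic response surface over three coded factors
#'
#' y(x) = y_max + (x - x_opt)' Q (x - x_opt) + interactions, parameterized
#' directly by its interior optimum so the ground truth is known exactly.
#' The quadratic part must be negative definite.
#'
#' @param optimum Coded coordinates of the maximum (inside \[-1, 1\]^3).
#' @param y_max Response value at the optimum (default 9.6 lg CFU/mL).
#' @param curvature 3x3 symmetric negative-definite matrix (default
#'   diag(-0.5, -0.4, -0.6) with -0.05 off-diagonal interactions).
#' @return List of class `quad_surface` with a `value(x)` function, the
#'   `optimum` and `y_max`.
#' @export
quad_surface <- function(optimum = c(0.25, -0.3, 0.2), y_max = 9.6,
                         curvature = NULL) {
  if (is.null(curvature)) {
    curvature <- diag(c(-0.5, -0.4, -0.6))
    curvature[upper.tri(curvature)] <- curvature[lower.tri(curvature)] <- -0.05
  }
  curvature <- (curvature + t(curvature)) / 2
  if (any(eigen(curvature, symmetric = TRUE, only.values = TRUE)$values >= 0))
    stop("curvature must be negative definite (interior maximum)")
  if (length(optimum) != 3L) stop("optimum must have 3 coordinates")
  force(y_max)
  value <- function(x) {
    x <- as.numeric(x) - optimum
    y_max + as.numeric(t(x) %*% curvature %*% x)
  }
  structure(list(value = value, optimum = optimum, y_max = y_max,
                 curvature = curvature),
            class = "quad_surface")
}

#' Closed-form argmax of a quadratic surface
#'
#' For a surface y = b0 + L'x + x'Qx the stationary point solves
#' 2Qx = -L; with the [quad_surface()] parameterization this returns the
#' stored optimum, providing a linear-algebra cross-check.
#'
#' @param surface A `quad_surface`.
#' @return Coded coordinates of the maximum.
#' @export
surface_argmax <- function(surface) {
  stopifnot(inherits(surface, "quad_surface"))
  # expand value(x) = y_max + (x-o)'Q(x-o) = const + L'x + x'Qx with L = -2Qo
  Q <- surface$curvature
  L <- -2 * Q %*% surface$optimum
  as.vector(solve(2 * Q, -L))
}

#' Simulate Box-Behnken responses from a quadratic surface
#'
#' Evaluates the surface at the coded design runs and adds seeded Gaussian
#' noise; center replicates differ only by noise.
#'
#' @param design A `bb_design` from [box_behnken()].
#' @param surface A `quad_surface`.
#' @param noise_sd Gaussian noise sd on the response (default 0.02 lg).
#' @param seed Integer seed.
#' @return The design with a `response` column appended.
#' @export
simulate_bbd <- function(design, surface, noise_sd = 0.02, seed = 1L) {
  stopifnot(inherits(design, "bb_design"), inherits(surface, "quad_surface"),
            noise_sd >= 0)
  coded <- as.matrix(design[, grep("_coded$", names(design))])
  y <- apply(coded, 1, surface$value)
  set.seed(seed)
  design$response <- y + stats::rnorm(length(y), sd = noise_sd)
  design
}

#' Parameter- and optimum-recovery experiments
#'
#' Monte Carlo harness quantifying how well the pipeline recovers known
#' ground truth from synthetic data. Stage `"kinetics"` simulates noisy
#' fermentation series and refits the growth model, reporting the error of
#' each coefficient; stage `"ann_ga"` simulates Box-Behnken responses from a
#' quadratic surface, trains the surrogate, runs the GA on the negated
#' surrogate, and reports the per-variable distance of the found optimum
#' from the truth as a fraction of the coded range.
#'
#' @param stage `"kinetics"` or `"ann_ga"`.
#' @param n_reps Number of seeded replicates.
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param noise_sd Noise level: growth-channel sd for kinetics (default
#'   0.02), response sd for ann_ga (default 0.01).
#' @param ga_max_gen GA generation cap for the ann_ga stage (default 120).
#' @param n_hidden,decay,n_starts Surrogate configuration for the ann_ga
#'   stage. Defaults: 8 hidden units, fixed weight decay 0.01, 3 restarts.
#'   An interior optimum is only representable when the network carries at
#'   least two tanh units per curvature direction (a sum of three monotone
#'   ridge functions has no strict interior maximum), and with only 15
#'   design points the evidence updates are ill-posed, so the harness uses
#'   a wider net with fixed decay and keeps the best restart.
#' @return Data frame with one row per replicate; kinetics rows carry
#'   relative coefficient errors (`rel_err_a` ... `rel_err_d`), ann_ga rows
#'   carry `err_frac_1..3` (fraction of each variable's range) and the
#'   training R-squared.
#' @export
recovery_experiment <- function(stage = c("kinetics", "ann_ga"), n_reps = 20L,
                                seed = 1L, noise_sd = NULL,
                                ga_max_gen = 120L, n_hidden = 8L,
                                decay = 0.01, n_starts = 3L) {
  stage <- match.arg(stage)
  if (stage == "kinetics") {
    if (is.null(noise_sd)) noise_sd <- 0.02
    truth <- default_sim_params()$growth
    rows <- lapply(seq_len(n_reps), function(r) {
      series <- simulate_fermentation(
        noise_sd = c(viable_lg = noise_sd, lactate = 0.15,
                     glucose_consumed = 0.15),
        seed = seed + r)
      fit <- suppressWarnings(fit_growth(series))
      rel <- abs(coef(fit) - truth) / abs(truth)
      data.frame(rep = r, rel_err_a = rel[["a"]], rel_err_b = rel[["b"]],
                 rel_err_c = rel[["c"]], rel_err_d = rel[["d"]],
                 converged = fit$converged)
    })
    return(do.call(rbind, rows))
  }
  if (is.null(noise_sd)) noise_sd <- 0.01
  surface <- quad_surface()
  design <- box_behnken(list(x1 = c(-1, 0, 1), x2 = c(-1, 0, 1),
                             x3 = c(-1, 0, 1)), center_runs = 3L)
  rows <- lapply(seq_len(n_reps), function(r) {
    sim <- simulate_bbd(design, surface, noise_sd = noise_sd, seed = seed + r)
    coded <- as.matrix(sim[, grep("_coded$", names(sim))])
    surr <- fit_surrogate(coded, sim$response, seed = seed + r,
                          n_hidden = n_hidden, decay = decay,
                          n_starts = n_starts, max_epochs = 400L)
    cfg <- ga_config(cbind(rep(-1, 3), rep(1, 3)), max_gen = ga_max_gen,
                     seed = seed + r)
    res <- ga_minimize(negate_objective(function(x) surr$predict(rbind(x))),
                       cfg)
    err <- abs(res$best_point - surface$optimum) / 2  # coded range is 2
    data.frame(rep = r, err_frac_1 = err[1], err_frac_2 = err[2],
               err_frac_3 = err[3], train_r2 = surr$metrics$r_squared,
               ga_generations = res$generations)
  })
  do.call(rbind, rows)
}
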