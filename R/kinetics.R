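# Logistic increment g(t) = a e^{ct} / D(t) and its denominator
# D(t) = 1 - (a/b)(1 - e^{ct}); the growth curve is X(t) = g(t) + d.
.logistic_denom <- function(t, a, b, c) 1 - (a / b) * (1 - exp(c * t))

.logistic_increment <- function(t, a, b, c) {
  D <- .logistic_denom(t, a, b, c)
  if (any(D <= 0))
    stop("logistic denominator 1 - (a/b)(1 - e^{ct}) is non-positive at t = ",
         paste(t[D <= 0], collapse = ", "))
  a * exp(c * t) / D
}

.par <- function(p, nm) {
  v <- unlist(p)[nm]
  if (any(is.na(v))) stop("missing parameter(s): ",
                          paste(nm[is.na(v)], collapse = ", "))
  unname(v)
}

#' Evaluate the offset logistic growth model
#'
#' Closed-form solution of the logistic law dX/dt = c X (1 - X/b) applied to
#' the biomass increment, plus a baseline offset for the non-zero initial
#' load: X(t) = a e^{ct} / \[1 - (a/b)(1 - e^{ct})\] + d.
#'
#' @param t Time, hours (vectorized).
#' @param params Named vector or list with `a` (initial logistic increment,
#'   lg CFU/mL), `b` (carrying-capacity increment, lg CFU/mL), `c` (maximum
#'   specific growth rate, 1/h), `d` (baseline initial load, lg CFU/mL).
#' @return Viable count, lg CFU/mL.
#' @examples
#' eval_growth(0, c(a = 0.04773, b = 2.106, c = 0.683, d = 7.582))  # = a + d
#' @export
eval_growth <- function(t, params) {
  p <- .par(params, c("a", "b", "c", "d"))
  if (p[1] <= 0 || p[2] <= 0 || p[3] <= 0 || p[4] < 0 || p[1] > p[2])
    stop("invalid growth parameters: need 0 < a <= b, c > 0, d >= 0")
  .logistic_increment(t, p[1], p[2], p[3]) + p[4]
}

#' Evaluate the Luedeking-Piret product-formation model
#'
#' Integrated form P(t) = P0 + m g(t) + (n b / c) ln D(t), where g(t) is the
#' logistic increment and D(t) its denominator. `m` is the growth-associated
#' and `n` the non-growth-associated production coefficient.
#'
#' @param t Time, hours.
#' @param params Named vector/list with `p0`, `m`, `n` and the shared logistic
#'   parameters `a`, `b`, `c`.
#' @return Product concentration, g/L.
#' @export
eval_product <- function(t, params) {
  p <- .par(params, c("p0", "m", "n", "a", "b", "c"))
  g <- .logistic_increment(t, p[4], p[5], p[6])
  D <- .logistic_denom(t, p[4], p[5], p[6])
  p[1] + p[2] * g + (p[3] * p[5] / p[6]) * log(D)
}

#' Evaluate the modified Luedeking-Piret substrate-consumption model
#'
#' Integrated form S(t) = S0 - M g(t) - (N b / c) ln D(t); the mirror image
#' of [eval_product()] with consumption coefficients `M` (growth-associated)
#' and `N` (maintenance).
#'
#' @param t Time, hours.
#' @param params Named vector/list with `s0`, `M`, `N`, `a`, `b`, `c`.
#' @return Residual substrate concentration, g/L.
#' @export
eval_substrate <- function(t, params) {
  p <- .par(params, c("s0", "M", "N", "a", "b", "c"))
  g <- .logistic_increment(t, p[4], p[5], p[6])
  D <- .logistic_denom(t, p[4], p[5], p[6])
  p[1] - p[2] * g - (p[3] * p[5] / p[6]) * log(D)
}

#' Right-hand sides of the kinetic ODE system
#'
#' Differential forms matching the closed-form curves, expressed on the
#' logistic increment x (so the growth offset `d` does not appear):
#' dx/dt = c x (1 - x/b); dP/dt = m dx/dt + n x; dS/dt = -M dx/dt - N x.
#' Intended for numeric-integration cross-checks of the closed forms.
#'
#' @param kind One of `"growth"`, `"product"`, `"substrate"`.
#' @param state Named state vector: `x` for growth; `x` plus `p` or `s` for
#'   the coupled systems.
#' @param t Time (unused; the system is autonomous).
#' @param params Parameters as in the corresponding `eval_*` function.
#' @return Named vector of derivatives matching `state`.
#' @export
ode_rhs <- function(kind, state, t, params) {
  kind <- match.arg(kind, c("growth", "product", "substrate"))
  x <- .par(state, "x")
  p <- unlist(params)
  dx <- p[["c"]] * x * (1 - x / p[["b"]])
  switch(kind,
    growth = c(x = dx),
    product = c(x = dx, p = p[["m"]] * dx + p[["n"]] * x),
    substrate = c(x = dx, s = -p[["M"]] * dx - p[["N"]] * x))
}

#' Coefficient constraints for kinetic fitting
#'
#' Builds a constraint table (start value, lower and upper bound per
#' coefficient; a coefficient with `lower == upper` is held fixed and excluded
#' from the optimization and from the residual degrees of freedom).
#'
#' @param coef Character vector of coefficient names.
#' @param start,lower,upper Numeric vectors aligned with `coef`;
#'   `lower <= start <= upper` must hold.
#' @return Data frame of class `kin_constraints`.
#' @export
kin_constraints <- function(coef, start, lower, upper) {
  n <- length(coef)
  if (length(start) != n || length(lower) != n || length(upper) != n)
    stop("coef/start/lower/upper must have equal length")
  if (any(lower > start | start > upper))
    stop("need lower <= start <= upper for every coefficient")
  out <- data.frame(coef = coef, start = start, lower = lower, upper = upper,
                    fixed = lower == upper, stringsAsFactors = FALSE)
  class(out) <- c("kin_constraints", "data.frame")
  out
}

#' Default constraint tables for the three kinetic models
#'
#' The published fitting protocol: growth coefficients all start near the
#' data and are bounded below by 0; the product and substrate fits hold the
#' growth coefficients `a` and `c` fixed (at the growth fit's estimates,
#' rounded to 4 decimals as in the study's constraint tables) and re-fit the
#' carrying capacity `b` from 2 upward.
#'
#' @param model `"growth"`, `"product"` or `"substrate"`.
#' @param growth_fit Optional `kinetic_fit` from [fit_growth()]; if supplied,
#'   its `a` and `c` (rounded to 4 decimals) replace the published fixed
#'   values in the product/substrate tables.
#' @return A `kin_constraints` table.
#' @export
default_constraints <- function(model = c("growth", "product", "substrate"),
                                growth_fit = NULL) {
  model <- match.arg(model)
  a_fix <- 0.0477
  c_fix <- 0.683
  if (!is.null(growth_fit)) {
    stopifnot(inherits(growth_fit, "kinetic_fit"))
    a_fix <- round(growth_fit$params[["a"]], 4)
    c_fix <- round(growth_fit$params[["c"]], 4)
  }
  switch(model,
    growth = kin_constraints(
      coef = c("a", "b", "c", "d"),
      start = c(0.05, 2, 0.5, 7.6),
      lower = c(0, 0, 0, 0),
      upper = c(Inf, Inf, Inf, Inf)),
    product = kin_constraints(
      coef = c("p0", "a", "b", "c", "m", "n"),
      start = c(0, a_fix, 2, c_fix, 0.9, 0.02),
      lower = c(0, a_fix, 2, c_fix, -Inf, -Inf),
      upper = c(Inf, a_fix, 10, c_fix, Inf, Inf)),
    substrate = kin_constraints(
      coef = c("s0", "a", "b", "c", "M", "N"),
      start = c(0, a_fix, 2, c_fix, 0.9, 0.02),
      lower = c(-Inf, a_fix, 2, c_fix, -Inf, -Inf),
      upper = c(Inf, a_fix, Inf, c_fix, Inf, Inf)))
}

#' Goodness-of-fit metrics for a kinetic fit
#'
#' R-squared about the observed mean and RMSE with denominator
#' n - p, where p counts only the freely estimated coefficients.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @param n_free_params Number of freely estimated coefficients.
#' @return List with `r_squared`, `rmse`, `sse`.
#' @export
gof_metrics <- function(observed, predicted, n_free_params) {
  n <- length(observed)
  if (length(predicted) != n) stop("observed and predicted lengths differ")
  dfe <- n - n_free_params
  if (dfe < 1) stop("need at least n_free_params + 1 observations")
  sse <- sum((observed - predicted)^2)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("zero total sum of squares: R-squared is undefined")
  list(r_squared = 1 - sse / sst, rmse = sqrt(sse / dfe), sse = sse)
}

# Bound-constrained Levenberg-Marquardt fit of `model_fun(t, full_params)`
# to `y`; fixed coefficients substituted, excluded from dfe and covariance.
.fit_kinetic <- function(t, y, constraints, model_fun, model_name) {
  stopifnot(inherits(constraints, "kin_constraints"))
  free <- !constraints$fixed
  p_free <- sum(free)
  n <- length(y)
  if (n < p_free + 1)
    stop(model_name, " fit needs at least ", p_free + 1,
         " points for ", p_free, " free coefficients; got ", n)
  full <- stats::setNames(constraints$start, constraints$coef)
  expand <- function(theta) { full[free] <- theta; full }
  resid_fun <- function(theta) model_fun(t, expand(theta)) - y
  fit <- minpack.lm::nls.lm(
    par = constraints$start[free],
    lower = constraints$lower[free],
    upper = constraints$upper[free],
    fn = resid_fun,
    control = minpack.lm::nls.lm.control(
      maxiter = 1000, ftol = 1e-15, ptol = 1e-15, gtol = 1e-10))
  converged <- fit$info %in% 1:4
  if (!converged)
    warning(model_name, " fit did not converge: ", fit$message)
  params <- expand(fit$par)
  pred <- model_fun(t, params)
  gof <- gof_metrics(y, pred, p_free)
  dfe <- n - p_free
  # covariance from the linearized Jacobian at the solution
  J <- .num_jacobian(function(theta) model_fun(t, expand(theta)), fit$par)
  JtJ <- crossprod(J)
  sigma2 <- gof$sse / dfe
  cov <- tryCatch(solve(JtJ) * sigma2, error = function(e) NULL)
  structure(list(
    model = model_name,
    params = params,
    free = stats::setNames(free, constraints$coef),
    constraints = constraints,
    residuals = as.numeric(pred - y),
    fitted = as.numeric(pred),
    sse = gof$sse, r_squared = gof$r_squared, rmse = gof$rmse,
    dfe = dfe, cov = cov, singular = is.null(cov),
    converged = converged, iterations = fit$niter,
    message = fit$message),
    class = "kinetic_fit")
}

.num_jacobian <- function(f, x, eps = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    h <- eps * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  J
}

#' Fit the logistic growth model to a viable-count series
#'
#' Bound-constrained nonlinear least squares of the offset logistic curve
#' (see [eval_growth()]) to the `viable_lg` column.
#'
#' @param series A `ferm_series`.
#' @param constraints A `kin_constraints` for coefficients a, b, c, d;
#'   defaults to the published constraint table.
#' @return A `kinetic_fit` with coefficients, linearization covariance,
#'   R-squared, RMSE (denominator n - free parameters), residuals and
#'   convergence diagnostics.
#' @examples
#' fit <- fit_growth(load_builtin("table3"))
#' coef(fit)["c"]  # maximum specific growth rate, 1/h
#' @export
fit_growth <- function(series, constraints = default_constraints("growth")) {
  stopifnot(inherits(series, "ferm_series"))
  if (!setequal(constraints$coef, c("a", "b", "c", "d")))
    stop("growth constraints must cover exactly a, b, c, d")
  # raw model, not eval_growth: the solver may explore a > b, which the
  # strict parameter validation rejects but which is well-defined for t >= 0
  .fit_kinetic(series$time, series$viable_lg, constraints,
               function(t, p) .logistic_increment(t, p[["a"]], p[["b"]],
                                                  p[["c"]]) + p[["d"]],
               "growth")
}

#' Fit the Luedeking-Piret product model to a lactate series
#'
#' Fits the integrated product curve (see [eval_product()]) to the `lactate`
#' column with the growth coefficients `a` and `c` held fixed at the growth
#' fit's estimates (the published protocol); fixed coefficients are excluded
#' from the degrees of freedom.
#'
#' @param series A `ferm_series`.
#' @param constraints Constraint table for p0, a, b, c, m, n; defaults to the
#'   published one, with a and c taken from `growth_fit` when supplied.
#' @param growth_fit Optional `kinetic_fit` from [fit_growth()] supplying the
#'   fixed a and c.
#' @return A `kinetic_fit`.
#' @export
fit_product <- function(series, constraints = NULL, growth_fit = NULL) {
  stopifnot(inherits(series, "ferm_series"))
  if (is.null(constraints))
    constraints <- default_constraints("product", growth_fit)
  if (!setequal(constraints$coef, c("p0", "a", "b", "c", "m", "n")))
    stop("product constraints must cover exactly p0, a, b, c, m, n")
  .fit_kinetic(series$time, series$lactate, constraints,
               function(t, p) eval_product(t, p), "product")
}

#' Fit the modified Luedeking-Piret substrate model to a glucose series
#'
#' The series records cumulative glucose consumed; the residual-glucose
#' trajectory is reconstructed as `K - glucose_consumed` for a caller-chosen
#' constant `K` (initial glucose charge, g/L). All fitted quantities except
#' the intercept `s0` are invariant to `K`, and the fitted `s0` tracks `K`.
#'
#' @param series A `ferm_series`.
#' @param constraints Constraint table for s0, a, b, c, M, N; defaults to the
#'   published one.
#' @param growth_fit Optional `kinetic_fit` supplying the fixed a and c.
#' @param K Reconstruction constant (initial glucose, g/L); default 30.44.
#' @return A `kinetic_fit`.
#' @export
fit_substrate <- function(series, constraints = NULL, growth_fit = NULL,
                          K = 30.44) {
  stopifnot(inherits(series, "ferm_series"), is.finite(K))
  if (is.null(constraints))
    constraints <- default_constraints("substrate", growth_fit)
  if (!setequal(constraints$coef, c("s0", "a", "b", "c", "M", "N")))
    stop("substrate constraints must cover exactly s0, a, b, c, M, N")
  .fit_kinetic(series$time, K - series$glucose_consumed, constraints,
               function(t, p) eval_substrate(t, p), "substrate")
}

#' Confidence intervals for fitted kinetic coefficients
#'
#' Wald intervals estimate +/- t(level, dfe) x standard error from the
#' linearized-Jacobian covariance. Fixed coefficients get degenerate
#' intervals; a singular Jacobian yields unbounded intervals with a warning.
#'
#' @param fit A `kinetic_fit`.
#' @param level Confidence level, default 0.95.
#' @return Data frame with `coef`, `estimate`, `lower`, `upper`, `fixed`.
#' @export
confidence_intervals <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "kinetic_fit"), level > 0, level < 1)
  est <- fit$params
  lo <- hi <- est
  free_names <- names(est)[fit$free]
  if (fit$singular) {
    warning("singular Jacobian: intervals for free coefficients are unbounded")
    lo[free_names] <- -Inf
    hi[free_names] <- Inf
  } else {
    se <- sqrt(diag(fit$cov))
    tcrit <- stats::qt((1 + level) / 2, df = fit$dfe)
    lo[free_names] <- est[free_names] - tcrit * se
    hi[free_names] <- est[free_names] + tcrit * se
  }
  data.frame(coef = names(est), estimate = unname(est),
             lower = unname(lo), upper = unname(hi),
             fixed = unname(!fit$free), row.names = NULL)
}

#' @export
coef.kinetic_fit <- function(object, ...) object$params

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("Kinetic fit:", x$model, "model\n")
  ci <- tryCatch(confidence_intervals(x), warning = function(w) NULL)
  if (!is.null(ci)) {
    print(ci, digits = 5)
  } else {
    print(x$params, digits = 5)
  }
  cat(sprintf("R-squared %.4f | RMSE %.4f (dfe = %d) | %s in %d iterations\n",
              x$r_squared, x$rmse, x$dfe,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}
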