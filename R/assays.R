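#' Titratable acidity from an NaOH titration
#'
#' Total acid expressed as lactic acid: P = c (V1 - V0) k / V x 1000, with
#' `c` the titrant concentration (mol/L), `V1`/`V0` the titrant volumes for
#' sample and blank (mL), `k` the lactic acid conversion coefficient
#' (0.090 g/mmol) and `V` the sample volume (mL).
#'
#' @param c NaOH concentration, mol/L.
#' @param V1 Titrant volume for the sample, mL.
#' @param V0 Titrant volume for the blank, mL.
#' @param V Sample volume, mL.
#' @param k Lactic acid conversion coefficient, default 0.090.
#' @return Total acid content, g/L. Vectorized over all arguments.
#' @examples
#' titratable_acidity(c = 0.01, V1 = 12, V0 = 2, V = 2)  # 4.5 g/L
#' @export
titratable_acidity <- function(c, V1, V0, V, k = 0.090) {
  if (any(c <= 0)) stop("titrant concentration must be positive")
  if (any(V <= 0)) stop("sample volume must be positive")
  if (any(V0 < 0) || any(V1 < V0)) stop("need V1 >= V0 >= 0")
  c * (V1 - V0) * k / V * 1000
}

#' Fit a DNS glucose standard curve
#'
#' Ordinary least-squares line of absorbance on glucose concentration
#' (concentration on the abscissa, absorbance on the ordinate).
#'
#' @param concentrations Glucose concentrations of the standards, mg/mL.
#' @param absorbances Measured absorbances at 540 nm.
#' @return List of class `standard_curve`: `slope`, `intercept`, `r_squared`,
#'   `range` (calibration range of concentrations).
#' @export
fit_dns_curve <- function(concentrations, absorbances) {
  if (length(concentrations) != length(absorbances))
    stop("concentrations and absorbances lengths differ")
  if (length(concentrations) < 3) stop("need at least 3 calibration points")
  if (stats::var(concentrations) == 0) stop("calibration concentrations are constant")
  fit <- stats::lm(absorbances ~ concentrations)
  co <- stats::coef(fit)
  sst <- sum((absorbances - mean(absorbances))^2)
  r2 <- if (sst == 0) 1 else 1 - sum(stats::residuals(fit)^2) / sst
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 r_squared = r2, range = range(concentrations)),
            class = "standard_curve")
}

#' Predict absorbance from a standard curve
#'
#' @param curve A `standard_curve`.
#' @param concentration Glucose concentration, mg/mL.
#' @return Predicted absorbance.
#' @export
predict_absorbance <- function(curve, concentration) {
  stopifnot(inherits(curve, "standard_curve"))
  curve$intercept + curve$slope * concentration
}

#' Inverse-predict glucose concentration from absorbance
#'
#' (A - intercept) / slope; values outside the calibration range trigger an
#' extrapolation warning.
#'
#' @param curve A `standard_curve`.
#' @param A Absorbance reading(s).
#' @return Glucose concentration, mg/mL.
#' @export
glucose_from_absorbance <- function(curve, A) {
  stopifnot(inherits(curve, "standard_curve"))
  if (curve$slope == 0) stop("zero slope: curve is not invertible")
  x <- (A - curve$intercept) / curve$slope
  out_of_range <- x < curve$range[1] | x > curve$range[2]
  if (any(out_of_range))
    warning("inverse prediction extrapolates beyond the calibration range [",
            curve$range[1], ", ", curve$range[2], "] for ",
            sum(out_of_range), " value(s)")
  x
}

#' Apparent adsorption capacity of a resin
#'
#' q = delta_c / dose: adsorbed lactic acid (C0 - C, g/L) per g/L of resin.
#'
#' @param dose Resin dose, g/L; must be positive.
#' @param delta_c Adsorbed lactic acid C0 - C, g/L.
#' @return Apparent adsorption amount q. Vectorized.
#' @examples
#' apparent_adsorption(50, 6.9)  # 0.138
#' @export
apparent_adsorption <- function(dose, delta_c) {
  if (any(dose <= 0)) stop("resin dose must be positive (q is undefined at 0)")
  delta_c / dose
}

#' Fold change between two log10 counts
#'
#' 10^(lg_new - lg_ref): the linear-scale ratio of two viable counts given on
#' the lg CFU/mL scale.
#'
#' @param lg_new,lg_ref Viable counts, lg CFU/mL.
#' @param digits If non-NULL, round the fold change for display (the study
#'   reports one decimal).
#' @return Fold change (unrounded unless `digits` is given).
#' @examples
#' fold_change_from_lg(9.66, 9.04, digits = 1)   # 4.2
#' fold_change_from_lg(10.01, 9.04, digits = 1)  # 9.3
#' @export
fold_change_from_lg <- function(lg_new, lg_ref, digits = NULL) {
  if (any(!is.finite(lg_new)) || any(!is.finite(lg_ref)))
    stop("inputs must be finite")
  fc <- 10^(lg_new - lg_ref)
  if (!is.null(digits)) round(fc, digits) else fc
}
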