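#' The L9(3^3) orthogonal array skeleton
#'
#' Standard 9-run array for three 3-level factors in which every factor-pair
#' level combination occurs exactly once; the level pattern matches the
#' study's buffer-salt design.
#'
#' @param factors Character vector of 3 factor names.
#' @return 9 x 3 integer matrix of level codes with `factors` as column names.
#' @export
l9_design <- function(factors = c("factor1", "factor2", "factor3")) {
  stopifnot(length(factors) == 3L)
  m <- cbind(c(1, 1, 1, 2, 2, 2, 3, 3, 3),
             c(1, 2, 3, 1, 2, 3, 1, 2, 3),
             c(1, 2, 3, 2, 3, 1, 3, 1, 2))
  storage.mode(m) <- "integer"
  colnames(m) <- factors
  m
}

#' Main-effects ANOVA for an L9 orthogonal table
#'
#' Decomposes the corrected total sum of squares of the 9 responses into
#' three 2-df factor main effects and a 2-df residual:
#' SS_factor = sum over levels of (level sum)^2 / 3 - (grand sum)^2 / 9.
#' Reports F against the residual mean square, exact F(2, 2) p-values,
#' classical eta-squared (SS_factor / SS_total) and an intercept row with
#' SS = 9 x (grand mean)^2 mirroring the study's table layout.
#'
#' @param table An `orthogonal_table` with responses.
#' @return Data frame of class `anova_l9` with columns `source`, `ss`, `df`,
#'   `ms`, `f`, `p`, `eta_squared`; attributes `r_squared` (sum of factor
#'   eta-squared) and `grand_mean`.
#' @examples
#' main_effects_anova(load_builtin("table1"))
#' @export
main_effects_anova <- function(table) {
  stopifnot(inherits(table, "orthogonal_table"))
  factors <- names(table)[2:4]
  y <- table$response
  grand <- sum(y)
  ss_total <- sum((y - mean(y))^2)
  ss_fac <- vapply(factors, function(f) {
    lv <- table[[f]]
    sum(tapply(y, lv, sum)^2) / 3 - grand^2 / 9
  }, numeric(1))
  ss_res <- ss_total - sum(ss_fac)
  ms_res <- ss_res / 2
  if (ms_res <= .Machine$double.eps * ss_total)
    warning("residual mean square is (near) zero: F ratios are infinite")
  f_fac <- (ss_fac / 2) / ms_res
  p_fac <- stats::pf(f_fac, 2, 2, lower.tail = FALSE)
  intercept_ss <- 9 * mean(y)^2
  out <- data.frame(
    source = c("intercept", factors, "residual", "total"),
    ss = c(intercept_ss, ss_fac, ss_res, ss_total),
    df = c(1L, 2L, 2L, 2L, 2L, 8L),
    ms = c(intercept_ss, ss_fac / 2, ms_res, NA),
    f = c(intercept_ss / ms_res, f_fac, NA, NA),
    p = c(stats::pf(intercept_ss / ms_res, 1, 2, lower.tail = FALSE), p_fac,
          NA, NA),
    eta_squared = c(NA, ss_fac / ss_total, ss_res / ss_total, NA),
    row.names = NULL)
  attr(out, "r_squared") <- sum(ss_fac) / ss_total
  attr(out, "grand_mean") <- mean(y)
  class(out) <- c("anova_l9", "data.frame")
  out
}

#' Best level of each factor by mean response
#'
#' Per-factor argmax of the three level means; ties are broken toward the
#' lowest level index and flagged.
#'
#' @param table An `orthogonal_table`.
#' @return Data frame with `factor`, `best_level`, `level_mean`, `tie`.
#' @export
best_levels <- function(table) {
  stopifnot(inherits(table, "orthogonal_table"))
  factors <- names(table)[2:4]
  rows <- lapply(factors, function(f) {
    means <- tapply(table$response, table[[f]], mean)
    best <- which.max(means)  # which.max returns the first maximum
    data.frame(factor = f, best_level = as.integer(names(means)[best]),
               level_mean = unname(means[best]),
               tie = sum(means == max(means)) > 1L)
  })
  do.call(rbind, rows)
}

#' Tukey HSD comparisons of level means for one factor
#'
#' Studentized-range comparisons of the three level means of `factor`, using
#' the main-effects ANOVA residual mean square on 2 df.
#'
#' @param table An `orthogonal_table`.
#' @param factor Name of one of the table's factor columns.
#' @param conf_level Confidence level, default 0.95.
#' @return Data frame with one row per level pair: `diff` (mean difference),
#'   `lower`, `upper`, `p_adj`, `significant`.
#' @export
tukey_hsd <- function(table, factor, conf_level = 0.95) {
  stopifnot(inherits(table, "orthogonal_table"))
  if (!factor %in% names(table)[2:4])
    stop("unknown factor '", factor, "'; available: ",
         paste(names(table)[2:4], collapse = ", "))
  an <- suppressWarnings(main_effects_anova(table))
  ms_res <- an$ms[an$source == "residual"]
  df_res <- 2
  if (ms_res <= 0) {
    warning("zero residual mean square: comparisons are degenerate")
    ms_res <- .Machine$double.eps
  }
  means <- tapply(table$response, table[[factor]], mean)
  se <- sqrt(ms_res / 3)  # 3 observations per level mean
  pairs <- utils::combn(names(means), 2)
  qcrit <- stats::qtukey(conf_level, nmeans = 3, df = df_res)
  out <- apply(pairs, 2, function(pr) {
    d <- means[[pr[2]]] - means[[pr[1]]]
    q <- abs(d) / se
    data.frame(
      comparison = paste(pr[2], "-", pr[1]),
      diff = d,
      lower = d - qcrit * se,
      upper = d + qcrit * se,
      p_adj = stats::ptukey(q, nmeans = 3, df = df_res, lower.tail = FALSE))
  })
  out <- do.call(rbind, out)
  out$significant <- out$p_adj < (1 - conf_level)
  rownames(out) <- NULL
  out
}

#' Generate a Box-Behnken design for three 3-level factors
#'
#' The 12 edge-midpoint runs (all +/-1 pairs of two factors with the third at
#' its center) plus replicated center runs, decoded to physical units.
#'
#' @param factor_specs Named list of length 3; each element a numeric vector
#'   of the 3 levels (low, center, high) for that factor.
#' @param center_runs Number of center-point replicates (>= 1), default 3.
#' @return Data frame of class `bb_design` with coded columns
#'   (`<name>_coded`) and decoded physical columns.
#' @examples
#' box_behnken(list(glucose = c(10, 20, 30), peptone = c(20, 40, 60),
#'                  corn_juice = c(4, 8, 12)))
#' @export
box_behnken <- function(factor_specs, center_runs = 3L) {
  if (length(factor_specs) != 3L || is.null(names(factor_specs)))
    stop("`factor_specs` must be a named list of exactly 3 factors")
  for (nm in names(factor_specs)) {
    lv <- factor_specs[[nm]]
    if (length(lv) != 3L || any(diff(lv) <= 0))
      stop("factor '", nm, "' must have 3 strictly increasing levels")
  }
  pm <- expand.grid(c(-1, 1), c(-1, 1))
  edges <- do.call(rbind, lapply(utils::combn(3, 2, simplify = FALSE), function(ij) {
    m <- matrix(0, 4, 3)
    m[, ij[1]] <- pm[[1]]
    m[, ij[2]] <- pm[[2]]
    m
  }))
  coded <- rbind(edges, matrix(0, center_runs, 3))
  colnames(coded) <- names(factor_specs)
  decoded <- vapply(seq_len(3), function(j) {
    factor_specs[[j]][coded[, j] + 2]  # -1/0/+1 -> low/center/high
  }, numeric(nrow(coded)))
  colnames(decoded) <- names(factor_specs)
  out <- data.frame(run = seq_len(nrow(coded)), coded, decoded,
                    check.names = FALSE)
  names(out)[2:4] <- paste0(names(factor_specs), "_coded")
  attr(out, "center_runs") <- as.integer(center_runs)
  attr(out, "factor_specs") <- factor_specs
  class(out) <- c("bb_design", "data.frame")
  out
}
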