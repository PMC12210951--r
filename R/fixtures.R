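#' Construct a fermentation time series
#'
#' Bundles timed observations of viable count (lg CFU/mL), lactic acid (g/L)
#' and cumulative glucose consumed (g/L) into a validated data frame of class
#' `ferm_series`. Optional per-column standard deviations may be attached as
#' `<column>_sd`.
#'
#' @param time Sampling times in hours; non-negative, strictly increasing.
#' @param viable_lg Viable counts in lg CFU/mL; strictly positive.
#' @param lactate Lactic acid concentration, g/L; non-negative.
#' @param glucose_consumed Cumulative glucose consumed since inoculation, g/L;
#'   non-negative.
#' @param sd Optional named list of standard-deviation vectors
#'   (`viable_lg`, `lactate`, `glucose_consumed`), each the same length as
#'   `time`.
#' @return A data frame of class `ferm_series`.
#' @export
ferm_series <- function(time, viable_lg, lactate, glucose_consumed, sd = NULL) {
  n <- length(time)
  if (length(viable_lg) != n || length(lactate) != n || length(glucose_consumed) != n)
    stop("all columns must have the same length as `time` (", n, ")")
  if (any(!is.finite(time)) || any(time < 0))
    stop("`time` must be finite and non-negative")
  if (any(diff(time) <= 0)) {
    i <- which(diff(time) <= 0)[1]
    stop("`time` must be strictly increasing; rows ", i, " and ", i + 1,
         " have times ", time[i], " and ", time[i + 1])
  }
  if (any(viable_lg <= 0)) stop("`viable_lg` must be positive (lg CFU/mL)")
  if (any(lactate < 0)) stop("`lactate` must be non-negative")
  if (any(glucose_consumed < 0)) stop("`glucose_consumed` must be non-negative")
  out <- data.frame(time = as.numeric(time),
                    viable_lg = as.numeric(viable_lg),
                    lactate = as.numeric(lactate),
                    glucose_consumed = as.numeric(glucose_consumed))
  if (!is.null(sd)) {
    for (nm in names(sd)) {
      if (!nm %in% c("viable_lg", "lactate", "glucose_consumed"))
        stop("unknown sd column: ", nm)
      if (length(sd[[nm]]) != n) stop("sd column ", nm, " has wrong length")
      out[[paste0(nm, "_sd")]] <- as.numeric(sd[[nm]])
    }
  }
  class(out) <- c("ferm_series", "data.frame")
  out
}

#' Construct an L9 orthogonal table with responses
#'
#' A 9-run, 3-factor, 3-level orthogonal array plus a response column.
#' Validates balance (each factor takes each level exactly three times) and
#' pairwise orthogonality (each level pair of any two factors occurs exactly
#' once).
#'
#' @param levels A 9 x 3 matrix or data frame of factor level codes in 1..3.
#' @param response Numeric response per run (lg CFU/mL in the builtin table).
#' @param factors Character vector of 3 factor names.
#' @return Data frame of class `orthogonal_table` with columns `run`,
#'   one column per factor, and `response`.
#' @export
orthogonal_table <- function(levels, response,
                             factors = c("factor1", "factor2", "factor3")) {
  levels <- as.matrix(levels)
  if (!all(dim(levels) == c(9L, 3L))) stop("`levels` must be 9 runs x 3 factors")
  if (!all(levels %in% 1:3)) stop("factor level codes must be in {1, 2, 3}")
  if (length(response) != 9L) stop("`response` must have 9 values")
  for (j in 1:3)
    if (!all(tabulate(levels[, j], 3L) == 3L))
      stop("factor ", factors[j], " is unbalanced: each level must occur 3 times")
  for (i in 1:2) for (j in (i + 1):3) {
    pairs <- paste(levels[, i], levels[, j])
    if (anyDuplicated(pairs))
      stop("factors ", factors[i], " and ", factors[j],
           " are not orthogonal: duplicated level pair")
  }
  out <- data.frame(run = 1:9, levels, response = as.numeric(response))
  names(out)[2:4] <- factors
  class(out) <- c("orthogonal_table", "data.frame")
  out
}

#' Construct a resin adsorption table
#'
#' Doses of anion-exchange resin (g/L) with the adsorbed lactic acid
#' `delta_c` = C0 - C (g/L) measured at each dose.
#'
#' @param dose Resin dose, g/L; non-negative, strictly increasing.
#' @param delta_c Adsorbed lactic acid C0 - C, g/L; non-decreasing in dose.
#' @return Data frame of class `adsorption_table`.
#' @export
adsorption_table <- function(dose, delta_c) {
  if (length(dose) != length(delta_c)) stop("`dose` and `delta_c` lengths differ")
  if (any(dose < 0)) stop("`dose` must be non-negative")
  if (any(diff(dose) <= 0)) stop("`dose` must be strictly increasing")
  if (any(diff(delta_c) < 0)) stop("`delta_c` must be non-decreasing in dose")
  out <- data.frame(dose = as.numeric(dose), delta_c = as.numeric(delta_c))
  class(out) <- c("adsorption_table", "data.frame")
  out
}

#' Construct a resin addition-rate count table
#'
#' Hourly viable counts (lg CFU/mL) from 8 to 16 h for three resin addition
#' rates (bed volumes per hour).
#'
#' @param rates Character labels of the three rates (BV/h).
#' @param counts 3 x 9 matrix of viable counts, rows matching `rates`,
#'   columns the hours 8..16.
#' @return Data frame of class `rate_count_table` in long format with columns
#'   `rate`, `time`, `viable_lg`.
#' @export
rate_count_table <- function(rates, counts) {
  counts <- as.matrix(counts)
  if (length(rates) != 3L || !all(dim(counts) == c(3L, 9L)))
    stop("expected 3 rate rows x 9 hourly columns (8-16 h)")
  if (any(counts <= 0)) stop("viable counts must be positive")
  out <- data.frame(rate = rep(rates, each = 9L),
                    time = rep(8:16, times = 3L),
                    viable_lg = as.numeric(t(counts)))
  class(out) <- c("rate_count_table", "data.frame")
  out
}

# Printed study tables, means as published; sds kept where printed but the
# fitting routines use means only.
.builtin_tables <- function() {
  list(
    table1 = function() orthogonal_table(
      levels = cbind(c(1, 1, 1, 2, 2, 2, 3, 3, 3),
                     c(1, 2, 3, 1, 2, 3, 1, 2, 3),
                     c(1, 2, 3, 2, 3, 1, 3, 1, 2)),
      response = c(9.32, 9.43, 9.39, 9.38, 9.49, 9.30, 9.49, 9.46, 9.35),
      factors = c("sodium_acetate", "ammonium_citrate", "dipotassium_phosphate")),
    table3 = function() ferm_series(
      time = c(0, 2, 4, 6, 8, 10, 12, 14),
      viable_lg = c(7.63, 7.75, 8.15, 8.79, 9.38, 9.59, 9.66, 9.68),
      lactate = c(0, 0.36, 1.08, 2.88, 6.12, 7.83, 9.09, 9.99),
      glucose_consumed = c(0, 0.40, 1.20, 3.20, 6.30, 7.90, 9.00, 10.10),
      sd = list(viable_lg = c(0, 0.01, 0.02, 0.01, 0.03, 0.02, 0.02, 0.04),
                lactate = c(0, 0.02, 0.03, 0.04, 0.07, 0.08, 0.14, 0.07),
                glucose_consumed = c(0, 0.01, 0.02, 0.01, 0.03, 0.02, 0.05, 0.04))),
    table7 = function() adsorption_table(
      dose = c(0, 5, 10, 20, 40, 50, 60, 80),
      delta_c = c(0, 0.95, 1.55, 3.05, 5.8, 6.9, 8, 9)),
    table9 = function() rate_count_table(
      rates = c("0.5 BV/h", "1.0 BV/h", "1.5 BV/h"),
      counts = rbind(
        c(9.38, 9.55, 9.62, 9.67, 9.74, 9.71, 9.65, 9.62, 9.60),
        c(9.38, 9.63, 9.76, 9.79, 9.85, 9.76, 9.73, 9.72, 9.70),
        c(9.38, 9.70, 9.79, 9.79, 9.78, 9.75, 9.71, 9.57, 9.53)))
  )
}

#' Load a builtin study table
#'
#' The package ships the published study tables as validated fixtures:
#' `"table1"` (L9 buffer-salt design with viable-count responses), `"table3"`
#' (batch fermentation time series), `"table7"` (resin adsorption) and
#' `"table9"` (resin addition-rate counts).
#'
#' @param name One of `"table1"`, `"table3"`, `"table7"`, `"table9"`.
#' @return The corresponding validated table object.
#' @examples
#' load_builtin("table3")
#' @export
load_builtin <- function(name) {
  tabs <- .builtin_tables()
  if (!is.character(name) || length(name) != 1L || !name %in% names(tabs))
    stop("unknown builtin table '", paste(name, collapse = ","),
         "'; available: ", paste(names(tabs), collapse = ", "))
  tabs[[name]]()
}

#' Read a fermentation series from CSV
#'
#' Expects a header row with columns `time`, `viable_lg`, `lactate`,
#' `glucose_consumed` (extra columns are ignored with a warning). Values are
#' validated as in [ferm_series()].
#'
#' @param path Path to a CSV file (RFC-4180, UTF-8).
#' @return A `ferm_series`.
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path, check.names = TRUE, colClasses = "character")
  need <- c("time", "viable_lg", "lactate", "glucose_consumed")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("CSV ", path, " is missing column(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(df), c(need, paste0(need, "_sd")))
  if (length(extra))
    warning("ignoring extra column(s) in ", path, ": ", paste(extra, collapse = ", "))
  num <- function(col) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(x) & !(df[[col]] %in% c("", "NA")))
    if (length(bad))
      stop("non-numeric value '", df[[col]][bad[1]], "' in column ", col,
           ", row ", bad[1])
    x
  }
  sd_cols <- intersect(paste0(c("viable_lg", "lactate", "glucose_consumed"), "_sd"),
                       names(df))
  sds <- if (length(sd_cols)) {
    s <- lapply(sd_cols, num)
    names(s) <- sub("_sd$", "", sd_cols)
    s
  }
  ferm_series(num("time"), num("viable_lg"), num("lactate"),
              num("glucose_consumed"), sd = sds)
}

#' Write a fermentation series to CSV
#'
#' Writes decimal text that round-trips through [read_series_csv()] without
#' loss (up to 15 significant digits).
#'
#' @param series A `ferm_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  stopifnot(inherits(series, "ferm_series"))
  df <- as.data.frame(series)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
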