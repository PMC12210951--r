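#' Run a multi-stage analysis pipeline
#'
#' Executes named stages in order, writing one JSON report per stage plus a
#' run log. Every report embeds the global seed and a hash of the
#' configuration so a run can be reproduced exactly. Supported stages:
#' \describe{
#'   \item{fit_growth / fit_product / fit_substrate}{`data` is a builtin name
#'     (`"builtin:table3"`) or a CSV path; kinetic fit report.}
#'   \item{anova}{`data` names the builtin L9 table (`"builtin:table1"`);
#'     main-effects ANOVA report.}
#'   \item{simulate}{`kind` is `"fermentation"` or `"bbd"`; writes a CSV.}
#'   \item{ann_ga}{trains a surrogate on a simulated Box-Behnken surface and
#'     optimizes it with the GA; recovery report.}
#' }
#'
#' @param config List with `stages` (named list of per-stage parameter
#'   lists), optional `seed` (default 1) and optional `out_dir`.
#' @param out_dir Output directory; created if missing. Overrides
#'   `config$out_dir`.
#' @return Named list of stage results, invisibly; reports are written under
#'   `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = config$out_dir %||% tempfile("fermkin_run_")) {
  stopifnot(is.list(config))
  stages <- config$stages
  if (is.null(stages) || length(stages) == 0L) {
    warning("empty stage list: nothing to do")
    return(invisible(list()))
  }
  seed <- config$seed %||% 1L
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_hash <- .config_hash(config)
  meta <- list(seed = seed, config_hash = cfg_hash,
               package_version = as.character(utils::packageVersion("fermkin")))
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(...) cat(..., "\n", sep = "", file = log_path, append = TRUE)
  log_line("fermkin pipeline | seed ", seed, " | config ", cfg_hash)
  results <- list()
  for (nm in names(stages)) {
    stage <- stages[[nm]]
    kind <- stage$stage %||% nm
    log_line("stage ", nm, " (", kind, ")")
    res <- tryCatch(
      .run_stage(kind, stage, seed, out_dir, nm, meta),
      error = function(e) {
        log_line("stage ", nm, " FAILED: ", conditionMessage(e))
        stop("pipeline stage '", nm, "' failed: ", conditionMessage(e),
             call. = FALSE)
      })
    results[[nm]] <- res
  }
  invisible(results)
}

.config_hash <- function(config) {
  # order-stable polynomial rolling hash of the serialized config;
  # avoids a digest dependency (doubles stay exact below 2^53)
  s <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE,
                        force = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

.resolve_series <- function(data) {
  if (grepl("^builtin:", data)) load_builtin(sub("^builtin:", "", data))
  else read_series_csv(data)
}

.write_report <- function(obj, path, meta) {
  obj$meta <- meta
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  path
}

.fit_report <- function(fit) {
  ci <- suppressWarnings(confidence_intervals(fit))
  list(model = fit$model,
       coefficients = as.list(fit$params),
       free = as.list(fit$free),
       ci = ci,
       r_squared = fit$r_squared, rmse = fit$rmse, sse = fit$sse,
       dfe = fit$dfe, converged = fit$converged,
       iterations = fit$iterations, residuals = fit$residuals)
}

.run_stage <- function(kind, stage, seed, out_dir, nm, meta) {
  out_json <- file.path(out_dir, paste0(nm, ".json"))
  switch(kind,
    fit_growth = {
      series <- .resolve_series(stage$data %||% "builtin:table3")
      fit <- fit_growth(series)
      .write_report(.fit_report(fit), out_json, meta)
      fit
    },
    fit_product = {
      series <- .resolve_series(stage$data %||% "builtin:table3")
      gf <- if (isTRUE(stage$refit_growth)) fit_growth(series)
      fit <- fit_product(series, growth_fit = gf)
      .write_report(.fit_report(fit), out_json, meta)
      fit
    },
    fit_substrate = {
      series <- .resolve_series(stage$data %||% "builtin:table3")
      gf <- if (isTRUE(stage$refit_growth)) fit_growth(series)
      fit <- fit_substrate(series, growth_fit = gf, K = stage$K %||% 30.44)
      .write_report(.fit_report(fit), out_json, meta)
      fit
    },
    anova = {
      tab <- if (grepl("^builtin:", stage$data %||% "builtin:table1"))
        load_builtin(sub("^builtin:", "", stage$data %||% "builtin:table1"))
      else stop("anova stage requires a builtin orthogonal table")
      an <- main_effects_anova(tab)
      .write_report(list(anova = an, r_squared = attr(an, "r_squared"),
                         best_levels = best_levels(tab)), out_json, meta)
      an
    },
    simulate = {
      kind2 <- stage$kind %||% "fermentation"
      out_csv <- file.path(out_dir, paste0(nm, ".csv"))
      if (kind2 == "fermentation") {
        series <- simulate_fermentation(seed = stage$seed %||% seed)
        write_series_csv(series, out_csv)
        series
      } else {
        design <- box_behnken(list(x1 = c(-1, 0, 1), x2 = c(-1, 0, 1),
                                   x3 = c(-1, 0, 1)))
        sim <- simulate_bbd(design, quad_surface(),
                            seed = stage$seed %||% seed)
        utils::write.csv(as.data.frame(sim), out_csv, row.names = FALSE)
        sim
      }
    },
    ann_ga = {
      rec <- recovery_experiment("ann_ga", n_reps = stage$n_reps %||% 1L,
                                 seed = stage$seed %||% seed)
      .write_report(list(recovery = rec), out_json, meta)
      rec
    },
    stop("unknown stage kind '", kind, "'"))
}
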