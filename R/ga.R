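#' Configure the real-coded genetic algorithm
#'
#' Defaults follow the study's settings: population 50, at most 300
#' generations, crossover probability 0.8, elite fraction 0.05 (elite count
#' = ceiling(fraction x population), so 3 with the defaults), and a stall
#' rule that stops when the best fitness changes by less than `stall_tol`
#' over `stall_gen` consecutive generations.
#'
#' @param bounds 2-column matrix (or list of length-2 vectors), one row per
#'   variable, giving finite lower and upper bounds.
#' @param pop_size Population size, default 50.
#' @param max_gen Maximum generations, default 300.
#' @param pcross Per-pair probability of blend crossover, default 0.8.
#' @param elite_frac Elite fraction, default 0.05.
#' @param stall_gen Stall window in generations, default 20.
#' @param stall_tol Fitness-change tolerance, default 1e-6.
#' @param mutation_rate Per-gene mutation probability, default 0.1.
#' @param seed Integer seed.
#' @return List of class `ga_config`.
#' @export
ga_config <- function(bounds, pop_size = 50L, max_gen = 300L, pcross = 0.8,
                      elite_frac = 0.05, stall_gen = 20L, stall_tol = 1e-6,
                      mutation_rate = 0.1, seed = 1L) {
  if (is.list(bounds)) bounds <- do.call(rbind, bounds)
  bounds <- as.matrix(bounds)
  if (ncol(bounds) != 2L) stop("`bounds` needs two columns (lower, upper)")
  if (any(!is.finite(bounds))) stop("bounds must be finite")
  if (any(bounds[, 1] >= bounds[, 2])) stop("need lower < upper per variable")
  if (pop_size < 2L) stop("population size must be at least 2")
  if (pcross < 0 || pcross > 1) stop("crossover probability must be in [0, 1]")
  n_elite <- ceiling(elite_frac * pop_size)
  if (n_elite < 1L) n_elite <- 1L
  structure(list(bounds = bounds, n_vars = nrow(bounds),
                 pop_size = as.integer(pop_size), max_gen = as.integer(max_gen),
                 pcross = pcross, elite_frac = elite_frac,
                 n_elite = as.integer(n_elite),
                 stall_gen = as.integer(stall_gen), stall_tol = stall_tol,
                 mutation_rate = mutation_rate, seed = as.integer(seed)),
            class = "ga_config")
}

#' Negate an objective for GA minimization
#'
#' The GA minimizes fitness; maximizing an objective f is done by minimizing
#' the linear transformation f -> -f.
#'
#' @param f A function of a point (numeric vector) returning a scalar.
#' @return The function x -> -f(x).
#' @export
negate_objective <- function(f) {
  force(f)
  function(x) -f(x)
}

#' Minimize a fitness function with a real-coded genetic algorithm
#'
#' Seeded uniform initialization within the bounds; rank-based
#' stochastic-universal-sampling selection (weight 1 / sqrt(rank));
#' arithmetic blend crossover with mixing ratio ~ U(0, 1) applied per pair
#' with the configured probability; adaptive Gaussian mutation whose scale
#' decays with generation (1 / (1 + g/50)) and is clipped at the bounds;
#' elites copied unchanged, so the best fitness is monotone non-increasing.
#'
#' @param fitness Function of a point returning a finite scalar to minimize.
#' @param config A [ga_config()].
#' @return List of class `ga_result`: `best_point`, `best_fitness`,
#'   `best_objective` (= -best_fitness, the pre-negation scale),
#'   `generations`, `history` (data frame of per-generation best and mean
#'   fitness) and `termination`.
#' @examples
#' cfg <- ga_config(cbind(0, 1), pop_size = 20, max_gen = 50, seed = 1)
#' ga_minimize(function(x) (x - 0.3)^2, cfg)$best_point
#' @export
ga_minimize <- function(fitness, config) {
  stopifnot(inherits(config, "ga_config"))
  set.seed(config$seed)
  nv <- config$n_vars; np <- config$pop_size
  lo <- config$bounds[, 1]; hi <- config$bounds[, 2]
  rng <- hi - lo
  pop <- matrix(stats::runif(np * nv, rep(lo, each = np), rep(hi, each = np)),
                np, nv)
  eval_pop <- function(P) {
    f <- apply(P, 1, fitness)
    bad <- which(!is.finite(f))
    if (length(bad))
      stop("non-finite fitness at point (",
           paste(signif(P[bad[1], ], 6), collapse = ", "), ")")
    f
  }
  fit <- eval_pop(pop)
  best_hist <- mean_hist <- numeric(0)
  termination <- "max_generations"
  gen <- 0L
  repeat {
    gen <- gen + 1L
    ord <- order(fit)
    pop <- pop[ord, , drop = FALSE]
    fit <- fit[ord]
    best_hist <- c(best_hist, fit[1])
    mean_hist <- c(mean_hist, mean(fit))
    if (length(best_hist) > config$stall_gen) {
      window <- best_hist[(length(best_hist) - config$stall_gen):length(best_hist)]
      if (max(window) - min(window) < config$stall_tol) {
        termination <- "stall"
        break
      }
    }
    if (gen >= config$max_gen) break
    # selection: stochastic universal sampling on rank weights 1/sqrt(rank)
    n_children <- np - config$n_elite
    wts <- 1 / sqrt(seq_len(np))
    cum <- cumsum(wts / sum(wts))
    pointers <- (stats::runif(1) + seq_len(n_children) - 1) / n_children
    parents_idx <- findInterval(pointers, cum) + 1L
    parents_idx <- sample(parents_idx)  # decouple pairing from rank order
    children <- pop[parents_idx, , drop = FALSE]
    # blend crossover per consecutive pair
    for (i in seq_len(n_children %/% 2)) {
      if (stats::runif(1) < config$pcross) {
        u <- stats::runif(1)
        p1 <- children[2 * i - 1, ]; p2 <- children[2 * i, ]
        children[2 * i - 1, ] <- u * p1 + (1 - u) * p2
        children[2 * i, ] <- (1 - u) * p1 + u * p2
      }
    }
    # adaptive Gaussian mutation, scale decaying with generation
    scale <- 0.1 / (1 + gen / 50)
    mut <- matrix(stats::runif(n_children * nv) < config$mutation_rate,
                  n_children, nv)
    noise <- matrix(stats::rnorm(n_children * nv, sd = rep(scale * rng, each = n_children)),
                    n_children, nv)
    children <- children + mut * noise
    # clip to bounds
    children <- pmin(pmax(children, rep(lo, each = n_children)),
                     rep(hi, each = n_children))
    elite <- pop[seq_len(config$n_elite), , drop = FALSE]
    pop <- rbind(elite, children)
    fit <- c(fit[seq_len(config$n_elite)], eval_pop(children))
  }
  structure(list(best_point = pop[1, ], best_fitness = fit[1],
                 best_objective = -fit[1], generations = gen,
                 history = data.frame(generation = seq_len(gen),
                                      best = best_hist, mean = mean_hist),
                 termination = termination, config = config),
            class = "ga_result")
}

#' Sweep GA settings and summarize convergence
#'
#' Runs [ga_minimize()] over the cross product of the supplied setting
#' vectors, with `n_reps` seeded replicates per setting.
#'
#' @param fitness Fitness function to minimize.
#' @param config Base [ga_config()]; swept fields override it.
#' @param sweep Named list of numeric vectors over GA settings (e.g.
#'   `list(pop_size = c(30, 50, 100), pcross = c(0.6, 0.9))`).
#' @param n_reps Seeded replicates per setting, default 3.
#' @return Data frame: one row per setting x replicate with the setting
#'   values, `seed`, `best_fitness`, `generations`, `termination`.
#' @export
parameter_sweep <- function(fitness, config, sweep, n_reps = 3L) {
  stopifnot(inherits(config, "ga_config"), is.list(sweep))
  grid <- expand.grid(sweep, KEEP.OUT.ATTRS = FALSE)
  if (nrow(grid) == 0L) grid <- data.frame(.dummy = 1)
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    for (rep in seq_len(n_reps)) {
      cfg <- config
      for (nm in setdiff(names(grid), ".dummy")) cfg[[nm]] <- grid[i, nm]
      cfg$n_elite <- max(1L, ceiling(cfg$elite_frac * cfg$pop_size))
      cfg$seed <- config$seed + (i - 1L) * n_reps + rep - 1L
      res <- ga_minimize(fitness, cfg)
      row <- grid[i, , drop = FALSE]
      row$.dummy <- NULL
      row$seed <- cfg$seed
      row$best_fitness <- res$best_fitness
      row$generations <- res$generations
      row$termination <- res$termination
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
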