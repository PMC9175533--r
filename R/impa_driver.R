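#' Run the improved marine predators algorithm (IMPA)
#'
#' The full loop: uniform initialization, an opposition-based refinement of
#' the initial population, then `it_max` iterations each consisting of a
#' velocity-phase update (high / unit / low velocity by iteration third),
#' memory saving and Elite refresh, the FADs long-jump perturbation with its
#' own memory save and Elite refresh, and a per-iteration opposition merge.
#' Every candidate generated is evaluated, so a run costs exactly
#' `N_n * (3 * it_max + 2)` objective evaluations.
#'
#' @param objective An [objective_adapter()] (or a `benchmark_objective`,
#'   which is adapted automatically).
#' @param space A `search_space`.
#' @param config An [optimizer_config()].
#' @return An `opt_result`: `best_position` (optimizer coordinates),
#'   `best_fitness` (minimization scale), `convergence` (best-so-far per
#'   iteration, non-increasing), `total_evaluations`, `seed`, `config`.
#' @export
run_impa <- function(objective, space, config = optimizer_config()) {
  run_mpa_family(objective, space, config, use_obl = TRUE)
}

#' Run the original marine predators algorithm (no opposition steps)
#'
#' Identical to [run_impa()] minus both opposition applications; costs
#' `N_n * (2 * it_max + 1)` evaluations.
#'
#' @inheritParams run_impa
#' @export
run_mpa <- function(objective, space, config = optimizer_config()) {
  run_mpa_family(objective, space, config, use_obl = FALSE)
}

run_mpa_family <- function(objective, space, config, use_obl) {
  objective <- as_objective(objective)
  rng <- rng_stream(config$seed)
  n <- config$N_n
  count0 <- eval_count(objective)

  prey <- sample_uniform(space, n, rng)
  fitness <- evaluate_rows(objective, prey, "initialization")

  if (use_obl) {
    opp <- opposite_population(prey, space)
    opp_fit <- evaluate_rows(objective, opp, "opposition initialization")
    merged <- greedy_merge(prey, fitness, opp, opp_fit)
    prey <- merged$prey
    fitness <- merged$fitness
  }
  state <- population_state(prey, fitness, space)

  # iterations are counted 0-based (it = 0 ... it_max-1), the original
  # MPA convention: the run opens at CF = 1 and the thirds split evenly
  it_max <- config$it_max
  b1 <- ceiling(it_max / 3)
  b2 <- ceiling(2 * it_max / 3)
  convergence <- numeric(it_max)

  for (it in seq.int(0L, it_max - 1L)) {
    ctx <- paste0("iteration ", it)
    if (it < b1) {
      state <- phase1_update(state, P = config$P, rng = rng)
    } else if (it < b2) {
      state <- phase2_update(state, it, it_max, P = config$P,
                             levy_exponent = config$levy_exponent, rng = rng)
    } else {
      state <- phase3_update(state, it, it_max, P = config$P,
                             levy_exponent = config$levy_exponent, rng = rng)
    }
    state$fitness <- evaluate_rows(objective, state$prey, ctx)
    state <- memory_save(state)
    state <- update_elite(state)

    cf <- compute_cf(it, it_max)
    state <- fads_perturbation(state, cf, config$FADs, rng)
    state$fitness <- evaluate_rows(objective, state$prey, paste0(ctx, " (FADs)"))
    state <- memory_save(state)
    state <- update_elite(state)

    if (use_obl) {
      opp <- opposite_population(state$prey, space)
      opp_fit <- evaluate_rows(objective, opp, paste0(ctx, " (opposition)"))
      merged <- greedy_merge(state$prey, state$fitness, opp, opp_fit)
      state$prey <- merged$prey
      state$fitness <- merged$fitness
      state$prev_prey <- state$prey
      state$prev_fitness <- state$fitness
      state <- update_elite(state)
    }
    convergence[it + 1L] <- state$best_fitness
  }

  used <- eval_count(objective) - count0
  expected <- if (use_obl) n * (3L * it_max + 2L) else n * (2L * it_max + 1L)
  stopifnot(used == expected)

  opt_result(
    optimizer = if (use_obl) "impa" else "mpa",
    best_position = state$best_position,
    best_fitness = state$best_fitness,
    convergence = convergence,
    total_evaluations = used,
    seed = config$seed,
    config = config,
    direction = objective$direction
  )
}

as_objective <- function(objective) {
  if (inherits(objective, "benchmark_objective")) {
    return(objective_adapter(objective$fn, "minimize"))
  }
  if (inherits(objective, "objective_adapter")) return(objective)
  if (is.function(objective)) return(objective_adapter(objective, "minimize"))
  stop("objective must be an objective_adapter, benchmark_objective or function",
       call. = FALSE)
}

opt_result <- function(optimizer, best_position, best_fitness, convergence,
                       total_evaluations, seed, config, direction = "minimize") {
  structure(list(
    optimizer = optimizer,
    best_position = best_position,
    best_fitness = best_fitness,
    best_value = if (direction == "maximize") -best_fitness else best_fitness,
    convergence = convergence,
    total_evaluations = total_evaluations,
    seed = seed,
    config = config,
    direction = direction
  ), class = "opt_result")
}

#' @export
print.opt_result <- function(x, ...) {
  cat(sprintf("opt_result [%s]  best fitness %.6g after %d evaluations (seed %d)\n",
              x$optimizer, x$best_fitness, x$total_evaluations, x$seed))
  invisible(x)
}

#' Uniform random-search baseline
#'
#' Best of `budget` uniform draws from the box; the equal-budget baseline
#' standing in for manual hyperparameter search.
#'
#' @inheritParams run_impa
#' @param budget Number of objective evaluations, `>= 1`.
#' @param seed Integer seed.
#' @export
run_random_search <- function(objective, space, budget, seed = 1) {
  stopifnot(budget >= 1)
  objective <- as_objective(objective)
  rng <- rng_stream(seed)
  count0 <- eval_count(objective)
  X <- sample_uniform(space, budget, rng)
  fit <- evaluate_rows(objective, X, "random search")
  best <- which.min(fit)
  opt_result(
    optimizer = "random",
    best_position = X[best, ],
    best_fitness = fit[best],
    convergence = cummin(fit),
    total_evaluations = eval_count(objective) - count0,
    seed = seed,
    config = list(budget = budget),
    direction = objective$direction
  )
}

#' Compare optimizers across seeds
#'
#' Runs each registered optimizer on the same objective over `n_seeds`
#' seeds and tabulates the distribution of best fitness.
#'
#' @param objective Objective (adapter, benchmark or function).
#' @param space A `search_space`.
#' @param optimizers Named list. Each entry is either a character shortcut
#'   (`"impa"`, `"mpa"`, `"random"`) or a function
#'   `function(objective, space, seed) -> opt_result` (the plug-in hook for
#'   external algorithms).
#' @param n_seeds Number of seeds (1, 2, ..., `n_seeds`).
#' @param config An [optimizer_config()] shared by the built-in optimizers;
#'   the random baseline gets a matched `N_n * (3 * it_max + 2)` budget.
#' @return A data.frame with one row per optimizer: median/mean/sd of best
#'   fitness and mean evaluation count.
#' @export
compare_optimizers <- function(objective, space,
                               optimizers = list(impa = "impa", mpa = "mpa"),
                               n_seeds = 10, config = optimizer_config()) {
  stopifnot(length(optimizers) >= 1)
  if (is.null(names(optimizers)) || any(!nzchar(names(optimizers)))) {
    stop("optimizers must be a named list", call. = FALSE)
  }
  resolve <- function(entry) {
    if (is.function(entry)) return(entry)
    switch(as.character(entry),
      impa = function(obj, sp, seed) {
        run_impa(obj, sp, modify_config(config, seed))
      },
      mpa = function(obj, sp, seed) {
        run_mpa(obj, sp, modify_config(config, seed))
      },
      random = function(obj, sp, seed) {
        run_random_search(obj, sp, config$N_n * (3L * config$it_max + 2L), seed)
      },
      stop("unknown optimizer '", entry, "'", call. = FALSE)
    )
  }
  rows <- lapply(names(optimizers), function(nm) {
    runner <- resolve(optimizers[[nm]])
    res <- lapply(seq_len(n_seeds), function(s) runner(objective, space, s))
    best <- vapply(res, `[[`, numeric(1), "best_fitness")
    evals <- vapply(res, `[[`, numeric(1), "total_evaluations")
    data.frame(optimizer = nm,
               median_best = stats::median(best),
               mean_best = mean(best),
               sd_best = stats::sd(best),
               mean_evaluations = mean(evals),
               n_seeds = n_seeds,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

modify_config <- function(config, seed) {
  config$seed <- as.integer(seed)
  config
}

#' Write a run's convergence curve and result files
#'
#' @param result An `opt_result`.
#' @param dir Output directory (created if missing).
#' @param space Optional `search_space`; when supplied the result JSON also
#'   carries the decoded best position.
#' @return Paths of the files written, invisibly.
#' @export
write_opt_result <- function(result, dir, space = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "convergence.csv")
  n_it <- length(result$convergence)
  per_iter <- result$total_evaluations / max(n_it, 1)
  utils::write.csv(
    data.frame(iteration = seq_len(n_it),
               best_fitness = result$convergence,
               evaluations = round(seq_len(n_it) * per_iter)),
    csv, row.names = FALSE)
  js <- file.path(dir, "result.json")
  payload <- list(
    optimizer = result$optimizer,
    best_fitness = result$best_fitness,
    best_position = as.numeric(result$best_position),
    total_evaluations = result$total_evaluations,
    seed = result$seed
  )
  if (!is.null(space)) {
    payload$best_decoded <- unclass(decode_position(result$best_position, space))
  }
  jsonlite::write_json(payload, js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv = csv, json = js))
}
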