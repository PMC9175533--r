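#' Optimizer configuration
#'
#' Run-control constants of the (I)MPA. Defaults follow the published
#' convention: step-scale constant `P = 0.5`, eddy/FADs probability
#' `FADs = 0.2`, population 30, 50 iterations, Levy tail index 1.5.
#'
#' @param N_n Population size; even and `>= 2` (the middle phase splits the
#'   population into halves).
#' @param it_max Maximum iterations, `>= 3` (one per phase at least).
#' @param P Step-scale constant.
#' @param FADs Probability of the long-jump (eddy) perturbation.
#' @param levy_exponent Tail index of the Levy sampler, in (1, 2\].
#' @param seed Integer seed for the run's random stream.
#' @return An `optimizer_config` object.
#' @export
optimizer_config <- function(N_n = 30, it_max = 50, P = 0.5, FADs = 0.2,
                             levy_exponent = 1.5, seed = 1) {
  if (N_n < 2 || N_n %% 2 != 0) stop("N_n must be even and >= 2", call. = FALSE)
  if (it_max < 3) stop("it_max must be >= 3", call. = FALSE)
  if (levy_exponent <= 1 || levy_exponent > 2) {
    stop("levy_exponent must lie in (1, 2]", call. = FALSE)
  }
  structure(list(N_n = as.integer(N_n), it_max = as.integer(it_max),
                 P = P, FADs = FADs, levy_exponent = levy_exponent,
                 seed = as.integer(seed)),
            class = "optimizer_config")
}

#' Population container
#'
#' Holds the prey matrix, its fitness, the Elite matrix (every row a copy
#' of the incumbent best vector), previous-iteration memory and the best
#' (position, fitness) pair. Constructed by the drivers; exposed so the
#' phase operators can be exercised directly.
#'
#' @param prey `N_n x Dim` position matrix (optimizer coordinates).
#' @param fitness Length-`N_n` fitness vector (minimization scale).
#' @param space The `search_space` the positions live in.
#' @return A `population_state`.
#' @export
population_state <- function(prey, fitness, space) {
  stopifnot(nrow(prey) == length(fitness))
  i <- which.min(fitness)
  st <- list(
    prey = prey,
    fitness = fitness,
    elite = matrix(prey[i, ], nrow = nrow(prey), ncol = ncol(prey), byrow = TRUE),
    best_position = prey[i, ],
    best_fitness = fitness[i],
    prev_prey = prey,
    prev_fitness = fitness,
    space = space
  )
  class(st) <- "population_state"
  st
}

#' High-velocity phase update (first third of the run)
#'
#' Prey outrun the predator: `stepsize = R_B * (Elite - R_B * prey)` with
#' Brownian multipliers `R_B`, and `prey <- prey + P * R * stepsize` with
#' `R` uniform in \[0,1\]. Result is clamped to the search box.
#'
#' @param state A `population_state`.
#' @param steps Optional list with entries `RB` (Brownian multiplier matrix)
#'   and `R` (uniform matrix), both `N_n x Dim`; drawn from `rng` when `NULL`.
#' @param P Step-scale constant.
#' @param rng An [rng_stream()] (unused when `steps` supplied).
#' @return The state with updated (clamped) prey.
#' @export
phase1_update <- function(state, steps = NULL, P = 0.5, rng = NULL) {
  n <- nrow(state$prey); d <- ncol(state$prey)
  if (is.null(steps)) {
    steps <- list(RB = brownian_matrix(n, d, rng),
                  R = matrix(rng_runif(rng, n * d), n, d))
  }
  stepsize <- steps$RB * (state$elite - steps$RB * state$prey)
  state$prey <- clamp_positions(state$prey + P * steps$R * stepsize, state$space)
  state
}

#' Unit-velocity phase update (middle third)
#'
#' The population splits: the first half keeps exploring with Levy steps
#' relative to its own position, `stepsize = R_L * (Elite - R_L * prey)`,
#' `prey <- prey + P * R * stepsize`; the second half exploits around the
#' Elite with Brownian steps, `stepsize = R_B * (R_B * Elite - prey)`,
#' `prey <- Elite + P * CF * stepsize`, where CF is [compute_cf()].
#'
#' @inheritParams phase1_update
#' @param it,it_max Iteration counters feeding the CF schedule.
#' @param levy_exponent Tail index of the Levy sampler.
#' @param steps Optional list with `RL`, `R` (first-half matrices) and `RB`
#'   (second-half matrix) for pinned-sample testing.
#' @export
phase2_update <- function(state, it, it_max, steps = NULL, P = 0.5,
                          levy_exponent = 1.5, rng = NULL) {
  n <- nrow(state$prey); d <- ncol(state$prey)
  if (n %% 2 != 0) stop("phase 2 requires an even population", call. = FALSE)
  h <- n %/% 2
  cf <- compute_cf(it, it_max)
  if (is.null(steps)) {
    steps <- list(RL = levy_matrix(h, d, levy_exponent, rng),
                  R = matrix(rng_runif(rng, h * d), h, d),
                  RB = brownian_matrix(h, d, rng))
  }
  top <- seq_len(h); bot <- seq.int(h + 1, n)
  step_top <- steps$RL * (state$elite[top, , drop = FALSE] -
                            steps$RL * state$prey[top, , drop = FALSE])
  state$prey[top, ] <- state$prey[top, , drop = FALSE] + P * steps$R * step_top
  step_bot <- steps$RB * (steps$RB * state$elite[bot, , drop = FALSE] -
                            state$prey[bot, , drop = FALSE])
  state$prey[bot, ] <- state$elite[bot, , drop = FALSE] + P * cf * step_bot
  state$prey <- clamp_positions(state$prey, state$space)
  state
}

#' Low-velocity phase update (final third)
#'
#' All rows exploit around the Elite with Levy steps:
#' `stepsize = R_L * (R_L * Elite - prey)`, `prey <- Elite + P * CF * stepsize`.
#'
#' @inheritParams phase2_update
#' @param steps Optional list with `RL` (`N_n x Dim`).
#' @export
phase3_update <- function(state, it, it_max, steps = NULL, P = 0.5,
                          levy_exponent = 1.5, rng = NULL) {
  n <- nrow(state$prey); d <- ncol(state$prey)
  cf <- compute_cf(it, it_max)
  if (is.null(steps)) {
    steps <- list(RL = levy_matrix(n, d, levy_exponent, rng))
  }
  stepsize <- steps$RL * (steps$RL * state$elite - state$prey)
  state$prey <- clamp_positions(state$elite + P * cf * stepsize, state$space)
  state
}

#' Eddy / fish-aggregating-devices perturbation
#'
#' With probability `FADs` a row takes a long jump toward a random box
#' point masked per-dimension (`prey <- prey + CF * (lb + r*(ub-lb)) * L`,
#' `L` a binary mask with activation probability `FADs`); otherwise it
#' drifts along the difference of two distinct random rows
#' (`prey <- prey + (FADs*(1-r) + r) * (prey_r1 - prey_r2)`). One uniform
#' scalar `r` is drawn per row. Clamped afterwards.
#'
#' @param state A `population_state`.
#' @param CF Current damping factor from [compute_cf()].
#' @param FADs Perturbation probability (default 0.2).
#' @param rng An [rng_stream()] (unused for any quantity pinned in `draws`).
#' @param draws Optional pinned random draws for single-step testing: list
#'   with `r` (length-`N_n` uniform scalars), `masks` (`N_n x Dim` binary
#'   matrix) and `pairs` (`N_n x 2` row-index matrix, distinct per row).
#' @return The state with perturbed (clamped) prey.
#' @export
fads_perturbation <- function(state, CF, FADs = 0.2, rng = NULL, draws = NULL) {
  n <- nrow(state$prey); d <- ncol(state$prey)
  b <- space_bounds(state$space)
  r_row <- if (!is.null(draws$r)) draws$r else rng_runif(rng, n)
  old_prey <- state$prey
  for (j in seq_len(n)) {
    r <- r_row[j]
    if (r <= FADs) {
      mask <- if (!is.null(draws$masks)) draws$masks[j, ] else fads_mask(d, FADs, rng)
      jump <- b$lb + r * (b$ub - b$lb)
      state$prey[j, ] <- old_prey[j, ] + CF * jump * mask
    } else {
      idx <- if (!is.null(draws$pairs)) draws$pairs[j, ] else rng_sample(rng, n, 2)
      state$prey[j, ] <- old_prey[j, ] +
        (FADs * (1 - r) + r) * (old_prey[idx[1], ] - old_prey[idx[2], ])
    }
  }
  state$prey <- clamp_positions(state$prey, state$space)
  state
}

#' Per-dimension binary FADs mask
#'
#' Indicator vector with activation probability `FADs` per dimension,
#' selecting which coordinates take part in a long jump.
#'
#' @param d Number of dimensions.
#' @param FADs Activation probability.
#' @param rng An [rng_stream()].
#' @return Numeric 0/1 vector of length `d`.
#' @export
fads_mask <- function(d, FADs, rng) {
  as.numeric(rng_runif(rng, d) < FADs)
}

#' Rowwise memory saving
#'
#' Each row keeps whichever of its current and previous-iteration
#' (position, fitness) pairs has the lower fitness, then the previous-
#' iteration copies are refreshed. Guarantees per-row fitness never
#' worsens across an iteration.
#'
#' @param state A `population_state` with evaluated `fitness`.
#' @return The updated state.
#' @export
memory_save <- function(state) {
  worse <- state$fitness > state$prev_fitness
  if (any(worse)) {
    state$prey[worse, ] <- state$prev_prey[worse, , drop = FALSE]
    state$fitness[worse] <- state$prev_fitness[worse]
  }
  state$prev_prey <- state$prey
  state$prev_fitness <- state$fitness
  state
}

#' Refresh the Elite matrix
#'
#' If the best current row strictly improves on the incumbent best fitness,
#' the incumbent is replaced and every Elite row becomes the new best
#' vector; ties keep the incumbent.
#'
#' @param state A `population_state` with evaluated `fitness`.
#' @return The updated state.
#' @export
update_elite <- function(state) {
  i <- which.min(state$fitness)
  if (state$fitness[i] < state$best_fitness) {
    state$best_fitness <- state$fitness[i]
    state$best_position <- state$prey[i, ]
    state$elite <- matrix(state$best_position, nrow = nrow(state$prey),
                          ncol = ncol(state$prey), byrow = TRUE)
  }
  state
}
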