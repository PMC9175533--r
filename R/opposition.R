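#' Opposition-based learning
#'
#' The opposite of an in-bounds point reflects it through the box centre:
#' `opposite(x) = lb + ub - x`, elementwise. Evaluating both a candidate
#' and its opposite and keeping the fitter of the pair probes the mirrored
#' region of the search space and accelerates convergence when the initial
#' population starts far from the optimum. Bounds are the static search-box
#' bounds in the optimizer's own coordinates (so log-searched dimensions
#' reflect linearly in log10 space).
#'
#' @param position Numeric vector (optimizer coordinates) within bounds.
#' @param space A `search_space`.
#' @return The opposite position vector.
#' @export
opposite <- function(position, space) {
  b <- space_bounds(space)
  if (length(position) != space$Dim) stop("position length != Dim", call. = FALSE)
  tol <- 1e-9 * pmax(1, abs(b$ub - b$lb))
  if (any(position < b$lb - tol) || any(position > b$ub + tol)) {
    stop("position outside bounds; opposite is only defined on the box",
         call. = FALSE)
  }
  b$lb + b$ub - position
}

#' @rdname opposite
#' @param prey An `n x Dim` matrix of in-bounds positions.
#' @return For `opposite_population`, a matrix of the same shape.
#' @export
opposite_population <- function(prey, space) {
  prey <- rbind_matrix(prey, space$Dim)
  b <- space_bounds(space)
  sweep(-prey, 2, b$lb + b$ub, `+`)
}

#' Greedy merge of a population with its opposite
#'
#' Rowwise, the (position, fitness) pair with the lower fitness is kept;
#' ties keep the original. Never increases any row's fitness.
#'
#' @param prey,fitness Original population and its fitness.
#' @param opp,opp_fitness Opposite population and its fitness.
#' @return A list with merged `prey` and `fitness`.
#' @export
greedy_merge <- function(prey, fitness, opp, opp_fitness) {
  if (!all(dim(prey) == dim(opp)) ||
      length(fitness) != nrow(prey) || length(opp_fitness) != nrow(opp)) {
    stop("prey/opposite shapes are misaligned", call. = FALSE)
  }
  take <- opp_fitness < fitness
  if (any(take)) {
    prey[take, ] <- opp[take, , drop = FALSE]
    fitness[take] <- opp_fitness[take]
  }
  list(prey = prey, fitness = fitness)
}
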