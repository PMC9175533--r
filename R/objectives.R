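#' Objective adapter
#'
#' Wraps a fitness function for the optimizer: handles orientation
#' (maximization objectives are negated internally; the optimizer always
#' minimizes) and counts evaluations.
#'
#' @param fn Function mapping a position vector (optimizer coordinates) to
#'   a scalar.
#' @param direction `"minimize"` or `"maximize"`.
#' @return An `objective_adapter`.
#' @export
objective_adapter <- function(fn, direction = c("minimize", "maximize")) {
  direction <- match.arg(direction)
  stopifnot(is.function(fn))
  env <- new.env(parent = emptyenv())
  env$count <- 0L
  obj <- list(fn = fn, direction = direction, env = env)
  class(obj) <- "objective_adapter"
  obj
}

# Evaluate every row of X; returns internal (minimization) fitness.
evaluate_rows <- function(objective, X, context = NULL) {
  n <- nrow(X)
  out <- numeric(n)
  for (j in seq_len(n)) {
    v <- tryCatch(objective$fn(X[j, ]), error = function(e) {
      where <- if (is.null(context)) "" else paste0(" at ", context)
      stop("objective evaluation failed", where, " (row ", j, "): ",
           conditionMessage(e), call. = FALSE)
    })
    if (!is.numeric(v) || length(v) != 1) {
      stop("objective must return a single number (row ", j, ")", call. = FALSE)
    }
    out[j] <- if (objective$direction == "maximize") -v else v
  }
  objective$env$count <- objective$env$count + n
  out
}

#' @rdname objective_adapter
#' @param objective An `objective_adapter`.
#' @export
eval_count <- function(objective) objective$env$count

#' Benchmark objective functions
#'
#' Classic bounded test problems with known optima, used to exercise and
#' compare the optimizers: `sphere` (`sum(x^2)`, minimum 0 at the origin),
#' `rastrigin` (multimodal, minimum 0 at the origin) and `rosenbrock`
#' (narrow curved valley, minimum 0 at the all-ones vector).
#'
#' @param name One of `"sphere"`, `"rastrigin"`, `"rosenbrock"`.
#' @param dimension Problem dimensionality, `>= 1`.
#' @param lower,upper Box bounds applied uniformly to every coordinate.
#' @return A `benchmark_objective`: list with `name`, `dimension`, `space`,
#'   `fn`, `global_minimum_position`, `global_minimum_value`.
#' @export
make_benchmark <- function(name, dimension = 8, lower = -10, upper = 10) {
  stopifnot(dimension >= 1)
  fn <- switch(name,
    sphere = function(x) sum(x^2),
    rastrigin = function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x)),
    rosenbrock = function(x) {
      if (length(x) < 2) return((1 - x[1])^2)
      sum(100 * (x[-1] - x[-length(x)]^2)^2 + (1 - x[-length(x)])^2)
    },
    stop("unknown benchmark '", name, "'", call. = FALSE)
  )
  opt_pos <- if (name == "rosenbrock") rep(1, dimension) else rep(0, dimension)
  dims <- lapply(seq_len(dimension), function(i) {
    dimension_spec(paste0("x", i), "continuous", lower, upper)
  })
  structure(list(
    name = name, dimension = dimension,
    space = search_space(dims),
    fn = fn,
    global_minimum_position = opt_pos,
    global_minimum_value = fn(opt_pos)
  ), class = "benchmark_objective")
}
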