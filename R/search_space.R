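#' Bounded search-space dimensions
#'
#' A search space is an ordered list of bounded dimensions over which the
#' optimizer moves. Three kinds are supported: `continuous` (the optimizer
#' coordinate is the value itself), `log_continuous` (the optimizer moves in
#' log10 space; bounds are given on the natural scale and must be positive),
#' and `integer` (decoded by rounding half-away-from-zero, then clamping).
#'
#' @param name Unique dimension name.
#' @param kind One of `"continuous"`, `"log_continuous"`, `"integer"`.
#' @param lower,upper Bounds on the natural scale, `lower < upper`.
#' @return A `dimension_spec` object.
#' @export
dimension_spec <- function(name, kind = c("continuous", "log_continuous", "integer"),
                           lower, upper) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  if (!is.numeric(lower) || !is.numeric(upper) || lower >= upper) {
    stop("dimension '", name, "': need lower < upper", call. = FALSE)
  }
  if (kind == "log_continuous" && (lower <= 0 || upper <= 0)) {
    stop("dimension '", name, "': log_continuous bounds must be positive", call. = FALSE)
  }
  if (kind == "integer" && (lower != round(lower) || upper != round(upper))) {
    stop("dimension '", name, "': integer bounds must be whole numbers", call. = FALSE)
  }
  structure(list(name = name, kind = kind, lower = lower, upper = upper),
            class = "dimension_spec")
}

#' Assemble a search space from dimension specs
#'
#' @param ... `dimension_spec` objects (or a single list of them).
#' @return A `search_space` with elements `dims` and `Dim`.
#' @export
search_space <- function(...) {
  dims <- list(...)
  if (length(dims) == 1 && is.list(dims[[1]]) && !inherits(dims[[1]], "dimension_spec")) {
    dims <- dims[[1]]
  }
  stopifnot(length(dims) >= 1)
  if (!all(vapply(dims, inherits, logical(1), "dimension_spec"))) {
    stop("all arguments must be dimension_spec objects", call. = FALSE)
  }
  nm <- vapply(dims, `[[`, character(1), "name")
  if (anyDuplicated(nm)) stop("dimension names must be unique", call. = FALSE)
  structure(list(dims = dims, Dim = length(dims)), class = "search_space")
}

#' @export
print.search_space <- function(x, ...) {
  cat("search_space with", x$Dim, "dimensions:\n")
  for (d in x$dims) {
    cat(sprintf("  %-16s %-15s [%g, %g]\n", d$name, d$kind, d$lower, d$upper))
  }
  invisible(x)
}

# Bounds in the optimizer's own coordinate system: log_continuous
# dimensions are searched in log10 space, everything else on the natural
# scale. All position matrices handled by the optimizer live in these
# coordinates.
space_bounds <- function(space) {
  lb <- vapply(space$dims, function(d) {
    if (d$kind == "log_continuous") log10(d$lower) else d$lower
  }, numeric(1))
  ub <- vapply(space$dims, function(d) {
    if (d$kind == "log_continuous") log10(d$upper) else d$upper
  }, numeric(1))
  list(lb = lb, ub = ub)
}

#' The default eight-dimensional classifier hyperparameter space
#'
#' Learning rate (log-continuous, 1e-7 to 1e-3), batch size (integer,
#' 1 to 64), three dropout rates (continuous, 0.1 to 0.9) and three
#' dense-layer unit counts (integer, 50 to 500), in that fixed order.
#' The learning rate is searched in log10 space because its range spans
#' four orders of magnitude.
#'
#' @return A `search_space` with `Dim = 8`.
#' @export
default_space <- function() {
  search_space(
    dimension_spec("learning_rate", "log_continuous", 1e-7, 1e-3),
    dimension_spec("batch_size", "integer", 1, 64),
    dimension_spec("dropout_1", "continuous", 0.1, 0.9),
    dimension_spec("dropout_2", "continuous", 0.1, 0.9),
    dimension_spec("dropout_3", "continuous", 0.1, 0.9),
    dimension_spec("dense_units_1", "integer", 50, 500),
    dimension_spec("dense_units_2", "integer", 50, 500),
    dimension_spec("dense_units_3", "integer", 50, 500)
  )
}

#' Map unit-cube coordinates onto a search space
#'
#' Each row of `Q` holds fractions in \[0,1\]; entry `q` maps to
#' `lb + q * (ub - lb)` in optimizer coordinates (so log-continuous
#' dimensions interpolate between the log10 bounds).
#'
#' @param space A `search_space`.
#' @param Q An `n x Dim` matrix with entries in \[0,1\].
#' @return An `n x Dim` position matrix in optimizer coordinates.
#' @export
position_from_unit <- function(space, Q) {
  Q <- as.matrix(Q)
  if (ncol(Q) != space$Dim) stop("Q must have Dim columns", call. = FALSE)
  b <- space_bounds(space)
  sweep(sweep(Q, 2, b$ub - b$lb, `*`), 2, b$lb, `+`)
}

#' Uniform sampling of initial positions
#'
#' Draws `n` positions uniformly in the box; log-continuous dimensions are
#' sampled uniformly in log10 space of their bounds.
#'
#' @param space A `search_space`.
#' @param n Number of positions (rows), `n >= 1`.
#' @param rng An [rng_stream()].
#' @return An `n x Dim` matrix in optimizer coordinates.
#' @export
sample_uniform <- function(space, n, rng) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n)) {
    stop("n must be a positive integer", call. = FALSE)
  }
  Q <- matrix(rng_runif(rng, n * space$Dim), nrow = n, ncol = space$Dim)
  position_from_unit(space, Q)
}

#' Project positions onto the search box
#'
#' Clamps every entry of a position matrix (optimizer coordinates) onto
#' its dimension's bounds. Idempotent.
#'
#' @param X Position matrix or vector.
#' @param space A `search_space`.
#' @return Clamped matrix of the same shape.
#' @export
clamp_positions <- function(X, space) {
  vec <- is.null(dim(X))
  X <- rbind_matrix(X, space$Dim)
  b <- space_bounds(space)
  X <- pmax(sweep(X * 0, 2, b$lb, `+`), pmin(sweep(X * 0, 2, b$ub, `+`), X))
  if (vec) drop(X) else X
}

rbind_matrix <- function(X, dim_n) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  if (ncol(X) != dim_n) stop("position has wrong number of columns", call. = FALSE)
  X
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Decode an optimizer position into a classifier configuration
#'
#' Continuous dimensions pass through after clamping; log-continuous
#' dimensions are exponentiated from their log10 coordinate; integer
#' dimensions are rounded half-away-from-zero, then clamped.
#'
#' @param position Numeric vector of length `Dim` (optimizer coordinates).
#' @param space A `search_space`.
#' @param epochs Fixed training epoch budget carried alongside the decoded
#'   values (not part of the search vector).
#' @return For [default_space()], a `classifier_config`; for other spaces a
#'   named list of decoded values.
#' @export
decode_position <- function(position, space, epochs = 30) {
  if (length(position) != space$Dim) {
    stop("position length ", length(position), " != Dim ", space$Dim, call. = FALSE)
  }
  position <- clamp_positions(position, space)
  vals <- numeric(space$Dim)
  for (i in seq_len(space$Dim)) {
    d <- space$dims[[i]]
    v <- position[i]
    vals[i] <- switch(d$kind,
      continuous = v,
      log_continuous = 10^v,
      integer = min(max(round_half_away(v), d$lower), d$upper)
    )
  }
  names(vals) <- vapply(space$dims, `[[`, character(1), "name")
  if (identical(names(vals), vapply(default_space()$dims, `[[`, character(1), "name"))) {
    return(classifier_config(
      learning_rate = vals[["learning_rate"]],
      batch_size = vals[["batch_size"]],
      dropout_rates = unname(vals[c("dropout_1", "dropout_2", "dropout_3")]),
      dense_units = unname(vals[c("dense_units_1", "dense_units_2", "dense_units_3")]),
      epochs = epochs
    ))
  }
  as.list(vals)
}

#' Classifier hyperparameter bundle
#'
#' The eight optimized hyperparameters of the transfer-learning classifier:
#' learning rate, batch size, three dropout rates and three dense-layer
#' widths, plus the fixed epoch budget.
#'
#' @param learning_rate Gradient-descent step size, in \[1e-7, 1e-3\].
#' @param batch_size Mini-batch size, integer in \[1, 64\].
#' @param dropout_rates Three dropout probabilities in \[0.1, 0.9\].
#' @param dense_units Three dense-layer widths, integers in \[50, 500\].
#' @param epochs Training epochs (fixed, default 30; not optimized).
#' @return A `classifier_config` object.
#' @export
classifier_config <- function(learning_rate, batch_size, dropout_rates,
                              dense_units, epochs = 30) {
  stopifnot(
    learning_rate >= 1e-7, learning_rate <= 1e-3,
    batch_size >= 1, batch_size <= 64, batch_size == round(batch_size),
    length(dropout_rates) == 3, all(dropout_rates >= 0.1), all(dropout_rates <= 0.9),
    length(dense_units) == 3, all(dense_units >= 50), all(dense_units <= 500),
    all(dense_units == round(dense_units)),
    epochs >= 1
  )
  structure(list(
    learning_rate = learning_rate,
    batch_size = as.integer(batch_size),
    dropout_rates = as.numeric(dropout_rates),
    dense_units = as.integer(dense_units),
    epochs = as.integer(epochs)
  ), class = "classifier_config")
}

#' @export
print.classifier_config <- function(x, ...) {
  cat("classifier_config\n")
  cat(sprintf("  learning_rate: %.3g\n", x$learning_rate))
  cat(sprintf("  batch_size:    %d\n", x$batch_size))
  cat(sprintf("  dropout_rates: %.3f %.3f %.3f\n",
              x$dropout_rates[1], x$dropout_rates[2], x$dropout_rates[3]))
  cat(sprintf("  dense_units:   %d %d %d\n",
              x$dense_units[1], x$dense_units[2], x$dense_units[3]))
  cat(sprintf("  epochs:        %d\n", x$epochs))
  invisible(x)
}

#' Serialize / deserialize a search space as YAML
#'
#' The on-disk form is a list of `{name, kind, lower, upper}` records.
#'
#' @param space A `search_space`.
#' @param path File path.
#' @export
space_to_yaml <- function(space, path) {
  recs <- lapply(space$dims, function(d) d[c("name", "kind", "lower", "upper")])
  yaml::write_yaml(recs, path)
  invisible(path)
}

#' @rdname space_to_yaml
#' @export
space_from_yaml <- function(path) {
  recs <- yaml::read_yaml(path)
  search_space(lapply(recs, function(r) {
    dimension_spec(r$name, r$kind, as.numeric(r$lower), as.numeric(r$upper))
  }))
}
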