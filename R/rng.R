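#' Seeded random-number stream
#'
#' All stochastic operations in the package draw from an explicit stream
#' object rather than the global generator, so that optimizer runs are
#' reproducible and never perturb (or depend on) `.Random.seed` in the
#' caller's session. A stream captures a Mersenne-Twister state seeded with
#' `seed`; each draw swaps the state in, samples, and swaps the caller's
#' state back.
#'
#' @param seed Integer seed.
#' @return An `rng_stream` object.
#' @export
rng_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  e <- new.env(parent = emptyenv())
  e$state <- NULL
  rng_eval(e, set.seed(as.integer(seed)))
  class(e) <- "rng_stream"
  e
}

# Evaluate `expr` with the stream's state installed as the global RNG state,
# then capture the advanced state and restore whatever the caller had.
rng_eval <- function(rng, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (!is.null(rng$state)) {
    assign(".Random.seed", rng$state, envir = globalenv())
  }
  on.exit({
    rng$state <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  eval.parent(substitute(expr))
}

#' @rdname rng_stream
#' @param rng An `rng_stream`.
#' @param n Number of draws.
#' @export
rng_runif <- function(rng, n) rng_eval(rng, stats::runif(n))

#' @rdname rng_stream
#' @export
rng_rnorm <- function(rng, n) rng_eval(rng, stats::rnorm(n))

#' @rdname rng_stream
#' @param x,size,replace As in [sample()].
#' @export
rng_sample <- function(rng, x, size, replace = FALSE) {
  rng_eval(rng, sample(x, size, replace = replace))
}

#' Derive a child stream from a parent stream
#'
#' Used by drivers to hand independent, reproducible sub-streams to
#' components (initialization, per-candidate training, ...) without
#' coupling their consumption rates.
#'
#' @param rng Parent stream.
#' @return A new `rng_stream`.
#' @export
rng_spawn <- function(rng) {
  rng_stream(floor(rng_runif(rng, 1) * 2147483646) + 1)
}
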