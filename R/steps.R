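#' Brownian step multipliers
#'
#' Standard-normal random multipliers modelling diffusive predator motion.
#'
#' @param rows,cols Matrix shape.
#' @param rng An [rng_stream()].
#' @return A `rows x cols` matrix of i.i.d. N(0,1) draws.
#' @export
brownian_matrix <- function(rows, cols, rng) {
  stopifnot(rows >= 1, cols >= 1)
  matrix(rng_rnorm(rng, rows * cols), nrow = rows, ncol = cols)
}

#' Levy-flight step multipliers (Mantegna construction)
#'
#' Heavy-tailed steps with tail index `exponent`, generated as
#' `u / |v|^(1/exponent)` where `u ~ N(0, sigma^2)`, `v ~ N(0, 1)` and
#' `sigma` is Mantegna's scale for the requested exponent. Occasional long
#' jumps let the search escape regions a Brownian walk would not leave.
#'
#' @param rows,cols Matrix shape.
#' @param exponent Tail index in (1, 2\]; default 1.5.
#' @param rng An [rng_stream()].
#' @return A `rows x cols` matrix of Levy-stable-like draws.
#' @export
levy_matrix <- function(rows, cols, exponent = 1.5, rng) {
  stopifnot(rows >= 1, cols >= 1)
  if (!is.numeric(exponent) || exponent <= 1 || exponent > 2) {
    stop("levy exponent must lie in (1, 2]", call. = FALSE)
  }
  a <- exponent
  sigma <- (gamma(1 + a) * sin(pi * a / 2) /
              (gamma((1 + a) / 2) * a * 2^((a - 1) / 2)))^(1 / a)
  u <- rng_rnorm(rng, rows * cols) * sigma
  v <- rng_rnorm(rng, rows * cols)
  matrix(u / abs(v)^(1 / a), nrow = rows, ncol = cols)
}

#' Adaptive step-damping factor CF
#'
#' `CF = (1 - it/it_max)^(2 * it/it_max)`: equals 1 at the first iteration
#' and decays monotonically to 0 at `it_max`, shrinking the Elite-anchored
#' step sizes as the search turns from exploration to exploitation.
#'
#' @param it Current iteration, `0 <= it <= it_max`.
#' @param it_max Maximum iterations.
#' @return A scalar in \[0, 1\].
#' @export
compute_cf <- function(it, it_max) {
  stopifnot(it >= 0, it <= it_max, it_max > 0)
  (1 - it / it_max)^(2 * it / it_max)
}
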