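# Shared fixtures built in code.

# 1-D space with generous bounds for hand-computed phase-update checks.
unit_line_space <- function(lower = -100, upper = 100) {
  search_space(dimension_spec("x", "continuous", lower, upper))
}

# population_state with explicit prey/elite for pinned-sample tests; the
# elite vector is installed as incumbent best regardless of prey fitness.
pinned_state <- function(prey, elite_vec, space) {
  prey <- matrix(prey, ncol = space$Dim)
  st <- population_state(prey, rep(1, nrow(prey)), space)
  st$best_position <- elite_vec
  st$best_fitness <- 0
  st$elite <- matrix(elite_vec, nrow = nrow(prey), ncol = space$Dim, byrow = TRUE)
  st
}

# Small separable image set shared by classifier tests (built once).
tiny_image_set <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_image_dataset(16, size = 32, separation = 4, seed = 101)
    }
    cache
  }
})
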