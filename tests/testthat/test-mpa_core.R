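test_that("high-velocity update matches the hand-evaluated rule", {
  sp <- unit_line_space()
  st <- pinned_state(3, 5, sp)
  # R_B = 1, R = 1, P = 0.5: step = 1*(5 - 1*3) = 2; prey = 3 + 0.5*2 = 4
  out <- phase1_update(st, steps = list(RB = matrix(1), R = matrix(1)), P = 0.5)
  expect_equal(out$prey[1, 1], 4)
  # all-zero Brownian multipliers leave prey unchanged
  out0 <- phase1_update(st, steps = list(RB = matrix(0), R = matrix(1)), P = 0.5)
  expect_equal(out0$prey, st$prey)
})

test_that("phase 1 with a live stream is deterministic and shape-preserving", {
  sp <- default_space()
  prey <- sample_uniform(sp, 6, rng_stream(1))
  st <- population_state(prey, rep(1, 6), sp)
  a <- phase1_update(st, P = 0.5, rng = rng_stream(9))
  b <- phase1_update(st, P = 0.5, rng = rng_stream(9))
  expect_identical(a$prey, b$prey)
  expect_equal(dim(a$prey), dim(prey))
})

test_that("unit-velocity update applies the split rules", {
  sp <- unit_line_space()
  # rows: 1 explorer (Levy), 1 exploiter (Brownian)
  st <- pinned_state(c(7, 1), 2, sp)
  # exploiter row, R_B=1, P=0.5, CF=0.5 (it=25/50):
  # step = 1*(1*2 - 1) = 1; prey = 2 + 0.5*0.5*1 = 2.25
  steps <- list(RL = matrix(0), R = matrix(0), RB = matrix(1))
  out <- phase2_update(st, it = 25, it_max = 50, steps = steps, P = 0.5)
  expect_equal(out$prey[2, 1], 2.25)
  expect_equal(out$prey[1, 1], 7)  # RL = 0 leaves the explorer in place

  # CF = 0 collapses the exploit half onto the Elite
  out0 <- phase2_update(st, it = 50, it_max = 50, steps = steps, P = 0.5)
  expect_equal(out0$prey[2, 1], 2)
})

test_that("exactly half the population receives the Levy rule", {
  sp <- default_space()
  n <- 10
  prey <- sample_uniform(sp, n, rng_stream(4))
  st <- population_state(prey, rep(1, n), sp)
  # zero out the Levy/R draws so the explorer half must stay put while
  # the Brownian half moves onto Elite-anchored positions
  h <- n / 2
  steps <- list(RL = matrix(0, h, sp$Dim), R = matrix(0, h, sp$Dim),
                RB = matrix(1, h, sp$Dim))
  out <- phase2_update(st, it = 50, it_max = 50, steps = steps, P = 0.5)
  expect_equal(out$prey[1:h, ], prey[1:h, ])
  expect_equal(out$prey[(h + 1):n, ], st$elite[(h + 1):n, ])
  st_odd <- population_state(prey[1:5, ], rep(1, 5), sp)
  expect_error(phase2_update(st_odd, 25, 50, rng = rng_stream(1)), "even")
})

test_that("low-velocity update matches the hand-evaluated rule", {
  sp <- unit_line_space()
  st <- pinned_state(1, 4, sp)
  # R_L=1, P=0.5, CF=1 (it=0): step = 1*(1*4 - 1) = 3; prey = 4 + 0.5*3 = 5.5
  out <- phase3_update(st, it = 0, it_max = 50,
                       steps = list(RL = matrix(1)), P = 0.5)
  expect_equal(out$prey[1, 1], 5.5)
  # CF = 0 collapses everything onto the Elite
  out0 <- phase3_update(st, it = 50, it_max = 50,
                        steps = list(RL = matrix(1)), P = 0.5)
  expect_equal(out0$prey[1, 1], 4)
})

test_that("phase outputs are always inside the search box", {
  sp <- search_space(dimension_spec("x", "continuous", -1, 1),
                     dimension_spec("y", "continuous", -2, 2))
  prey <- sample_uniform(sp, 8, rng_stream(3))
  st <- population_state(prey, rep(1, 8), sp)
  rng <- rng_stream(77)
  for (i in 1:20) {
    st1 <- phase1_update(st, P = 0.5, rng = rng)
    st2 <- phase2_update(st, 25, 50, P = 0.5, rng = rng)
    st3 <- phase3_update(st, 45, 50, P = 0.5, rng = rng)
    for (s in list(st1, st2, st3)) {
      expect_true(all(s$prey[, 1] >= -1 & s$prey[, 1] <= 1))
      expect_true(all(s$prey[, 2] >= -2 & s$prey[, 2] <= 2))
    }
  }
})

test_that("FADs else-branch with identical rows leaves prey unchanged", {
  sp <- unit_line_space(0, 10)
  prey <- matrix(c(4, 4), ncol = 1)
  st <- pinned_state(prey, 4, sp)
  # FADs = 0 forces the else branch; identical rows give zero displacement
  out <- fads_perturbation(st, CF = 1, FADs = 0, rng = rng_stream(13))
  expect_equal(out$prey, st$prey)
})

test_that("FADs branches match hand-computed displacements", {
  sp <- unit_line_space(0, 10)
  st <- pinned_state(c(2, 6), 2, sp)
  draws <- list(r = c(0.1, 0.9), masks = matrix(c(1, 1), 2, 1),
                pairs = rbind(c(1, 2), c(1, 2)))
  out <- fads_perturbation(st, CF = 0.5, FADs = 0.2, draws = draws)
  # row 1 (r = 0.1 <= 0.2): 2 + 0.5*(0 + 0.1*10)*1 = 2.5
  expect_equal(out$prey[1, 1], 2.5)
  # row 2 (r = 0.9): 6 + (0.2*0.1 + 0.9)*(2 - 6) = 6 - 0.92*4 = 2.32
  expect_equal(out$prey[2, 1], 6 + (0.2 * 0.1 + 0.9) * (2 - 6))
})

test_that("FADs mask activates at the configured rate", {
  m <- fads_mask(1e5, 0.2, rng_stream(31))
  expect_lt(abs(mean(m) - 0.2), 0.01)
})

test_that("memory saving keeps the rowwise better pair", {
  sp <- default_space()
  rng <- rng_stream(8)
  prey_new <- sample_uniform(sp, 12, rng)
  prey_old <- sample_uniform(sp, 12, rng)
  fit_new <- rng_runif(rng, 12)
  fit_old <- rng_runif(rng, 12)
  st <- population_state(prey_old, fit_old, sp)
  st$prey <- prey_new
  st$fitness <- fit_new
  out <- memory_save(st)
  for (j in 1:12) {  # brute-force rowwise oracle
    if (fit_new[j] <= fit_old[j]) {
      expect_equal(out$prey[j, ], prey_new[j, ])
      expect_equal(out$fitness[j], fit_new[j])
    } else {
      expect_equal(out$prey[j, ], prey_old[j, ])
      expect_equal(out$fitness[j], fit_old[j])
    }
  }
  expect_equal(out$prev_prey, out$prey)
  expect_equal(out$prev_fitness, out$fitness)

  # degenerate directions: all-better and all-worse
  st$fitness <- fit_old - 1
  expect_equal(memory_save(st)$prey, prey_new)
  st$fitness <- fit_old + 1
  expect_equal(memory_save(st)$prey, prey_old)
})

test_that("Elite updates on strict improvement only and replicates rows", {
  sp <- unit_line_space()
  st <- population_state(matrix(c(5, 9), ncol = 1), c(2, 3), sp)
  expect_equal(st$best_fitness, 2)
  # tie: incumbent kept
  st$prey[2, 1] <- -4
  st$fitness <- c(7, 2)
  out <- update_elite(st)
  expect_equal(out$best_position, st$best_position)
  expect_equal(unique(out$elite[, 1]), st$best_position)
  # strict improvement: all Elite rows replaced
  st$fitness <- c(7, 1.5)
  out2 <- update_elite(st)
  expect_equal(out2$best_fitness, 1.5)
  expect_equal(out2$elite, matrix(-4, 2, 1))
})
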