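# Closed-loop controller: deviations, update rules, loop harness.

test_that("deviations are elementwise differences and antisymmetric", {
  d <- compute_deviations(c(5, 3), c(4, 4))
  expect_equal(d$dY, c(1, -1))

  p_obs <- matrix(runif(6), 2, 3)
  p_pred <- matrix(runif(6), 2, 3)
  both <- compute_deviations(c(1, 1), c(1, 1), p_obs, p_pred)
  expect_equal(both$dp, p_obs - p_pred)

  swapped <- compute_deviations(c(4, 4), c(5, 3), p_pred, p_obs)
  expect_equal(swapped$dY, -d$dY)
  expect_equal(swapped$dp, -both$dp)

  expect_equal(compute_deviations(c(2, 2), c(2, 2))$dY, c(0, 0))
  expect_error(compute_deviations(1:3, 1:2), "length")
  expect_error(compute_deviations(c(1), c(1), matrix(0, 1, 2),
                                  matrix(0, 2, 2)), "shape")
})

test_that("allocation update follows the additive rule with clipping and projection", {
  st <- controller_state(alpha_r = c(0.1, 0.05, 0.01))
  U <- matrix(c(10, 5, 2), 1, 3)
  out <- update_allocation(U, dY = 2, st, caps = rep(Inf, 3),
                           budgets = rep(Inf, 3))
  expect_equal(drop(out), c(10.2, 5.1, 2.02), ignore_attr = TRUE)

  # zero deviation: bit-identical return
  expect_identical(update_allocation(U, 0, st, rep(Inf, 3), rep(Inf, 3)), U)

  # negative update clipped at zero
  u0 <- matrix(c(0.1, 0.1, 0.1), 1, 3)
  low <- update_allocation(u0, dY = -2, st, rep(Inf, 3), rep(Inf, 3))
  expect_equal(drop(low)[1], 0, ignore_attr = TRUE)

  # budget projection keeps the column within budget
  U2 <- matrix(c(4, 4, 0, 0, 0, 0), 2, 3)
  over <- update_allocation(U2, dY = c(10, 10), st, caps = rep(10, 3),
                            budgets = c(8.5, 10, 10))
  expect_lte(sum(over[, 1]), 8.5 + 1e-9)
  expect_true(all(over >= 0))
})

test_that("priority updates are linear and additive across deviation batches", {
  r <- c(1, 2)
  dp1 <- matrix(c(0.3, 0, 0, 0, 0, 0), 2, 3)
  beta_vec <- c(1, 0, 0)
  expect_equal(update_priorities(r, dp1, beta_vec), c(1.3, 2))
  expect_equal(update_priorities(r, matrix(0, 2, 3), beta_vec), r)

  dp2 <- matrix(rnorm(6), 2, 3)
  seq_update <- update_priorities(update_priorities(r, dp1, beta_vec),
                                  dp2, beta_vec)
  sum_update <- update_priorities(r, dp1 + dp2, beta_vec)
  expect_equal(seq_update, sum_update)

  expect_error(update_priorities(r, matrix(0, 3, 3), beta_vec), "shapes")
})

test_that("noiseless loop with a perfect predictor is a fixed point", {
  sc <- field_scenario(n_zones = 4, grid_shape = c(2, 2), noise_sd = 0,
                       seed = 5)
  plan <- solve_constrained(sc$true_params, sc$budgets, sc$caps, 4)
  tr <- run_closed_loop(sc, plan, controller_state(), T_steps = 20,
                        seed = 1)
  expect_true(all(tr$records$dY == 0))
  for (h in tr$history) expect_equal(h$U, tr$history[[1]]$U)
})

test_that("a biased predictor ramps allocations until constraints bind", {
  sc <- field_scenario(n_zones = 4, grid_shape = c(2, 2), noise_sd = 0,
                       seed = 5)
  biased <- local({
    pp <- perfect_predictor(sc)
    function(U, env) { o <- pp(U, env); o$y_hat <- o$y_hat - 1; o }
  })
  tr <- run_closed_loop(sc, matrix(1, 4, 3), controller_state(),
                        T_steps = 60, predictor = biased, seed = 1)
  totals <- vapply(tr$history, function(h) sum(h$U), numeric(1))
  expect_true(all(diff(totals) >= -1e-9))
  expect_gt(totals[60], totals[1])
  # eventually the per-zone water cap or budget binds: growth stops
  expect_lt(totals[60] - totals[55], 5 * sum(controller_state()$alpha_r) * 4)
  for (h in tr$history) {
    expect_true(all(h$U >= -1e-12))
    expect_true(all(h$U <= sc$caps + 1e-9))
    expect_true(all(colSums(h$U) <= sc$budgets + 1e-9))
  }
})

test_that("trajectories are reproducible from the seed and fully logged", {
  sc <- tiny_scenario(4, noise_sd = 0.3)
  plan <- solve_constrained(sc$true_params, sc$budgets, sc$caps, 4)
  a <- run_closed_loop(sc, plan, controller_state(), T_steps = 10, seed = 9)
  b <- run_closed_loop(sc, plan, controller_state(), T_steps = 10, seed = 9)
  expect_identical(a$records, b$records)
  expect_equal(nrow(a$records), 10 * 4 * 3)
  expect_equal(unique(a$records$resource),
               c("water", "fertilizer", "pesticide"))
  expect_true(all(diff(unique(a$records$t)) == 1))
})

test_that("priority reallocation mode keeps plans feasible", {
  sc <- tiny_scenario(4, noise_sd = 0.2)
  events <- list(stress_event(0, "drought", 0.8, onset = 2))
  tr <- run_closed_loop(sc, matrix(1, 4, 3), controller_state(),
                        T_steps = 12, seed = 4, events = events,
                        reallocate_every = 4)
  for (h in tr$history) {
    expect_true(all(h$U <= sc$caps + 1e-9))
    expect_true(all(colSums(h$U) <= sc$budgets + 1e-9))
  }
})
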