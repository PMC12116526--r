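# Field simulator: scenario construction, environment dynamics, stress
# injection, observation rendering and yield realization.

test_that("scenario generation is deterministic and validates its inputs", {
  a <- field_scenario(n_zones = 4, grid_shape = c(2, 2), seed = 7)
  b <- field_scenario(n_zones = 4, grid_shape = c(2, 2), seed = 7)
  expect_identical(a, b)

  expect_error(field_scenario(n_zones = 0), "n_zones")
  expect_error(field_scenario(n_zones = 4, grid_shape = c(2, 3)),
               "grid_shape")
  expect_error(field_scenario(n_zones = 2, caps = c(-1, 1, 1)), "caps")
  expect_error(
    field_scenario(n_zones = 1,
                   true_params = objective_params(gamma = -1)),
    "gamma")
})

test_that("zones map to grid cells row-major, 0-based", {
  sc <- field_scenario(n_zones = 9, grid_shape = c(3, 3))
  g <- zone_grid(sc)
  expect_equal(g$zone_id, 0:8)
  expect_equal(g$row, (0:8) %/% 3)
  expect_equal(g$col, (0:8) %% 3)
})

test_that("zero-noise unit-AR environment is a fixed point", {
  sc <- field_scenario(
    n_zones = 4, grid_shape = c(2, 2), seed = 3,
    env = list(ar = 1,
               innovation_sd = c(moisture = 0, temperature = 0,
                                 nutrient = 0, vigor = 0)),
    obs = list(weather_ar = 1, weather_sd = rep(0, 4)))
  e0 <- sample_environment(sc, 0)
  e1 <- sample_environment(sc, 1, e0)
  expect_equal(e1$p, e0$p)
  expect_equal(e1$weather, e0$weather)
})

test_that("innovation correlation between zones vanishes as the correlation length shrinks", {
  draws <- function(ell) {
    sc <- field_scenario(n_zones = 2, grid_shape = c(1, 2),
                         env_corr_length = ell, seed = 1)
    t(vapply(seq_len(1000),
             function(t) sample_environment(sc, t)$p[, "temperature"],
             numeric(2)))
  }
  d_long <- draws(5)
  d_short <- draws(1e-6)
  expect_gt(cor(d_long[, 1], d_long[, 2]), 0.8)
  expect_lt(abs(cor(d_short[, 1], d_short[, 2])), 0.1)
})

test_that("bounded environment variables stay in range", {
  sc <- field_scenario(n_zones = 4, grid_shape = c(2, 2), seed = 9,
                       env = list(innovation_sd = c(
                         moisture = 0.5, temperature = 1,
                         nutrient = 0.5, vigor = 0.5)))
  env <- NULL
  for (t in 0:99) {
    env <- sample_environment(sc, t, env)
    expect_true(all(env$p[, c("moisture", "nutrient", "vigor")] >= 0))
    expect_true(all(env$p[, c("moisture", "nutrient", "vigor")] <= 1))
  }
})

test_that("stress injection applies documented shifts to target zones only", {
  sc <- tiny_scenario(4)
  env <- sample_environment(sc, 0)
  env$p[, "moisture"] <- 0.6

  expect_equal(inject_stress(env, list(
    stress_event(0:3, "drought", severity = 0)), sc)$p, env$p)

  shifted <- inject_stress(env, list(
    stress_event(3, "drought", severity = 1)), sc)
  expect_equal(shifted$p[4, "moisture"], 0.2, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(shifted$p[1:3, "moisture"], env$p[1:3, "moisture"])

  ev_a <- stress_event(0, "drought", severity = 0.5)
  ev_b <- stress_event(2, "nutrient_deficiency", severity = 0.7)
  ab <- inject_stress(env, list(ev_a, ev_b), sc)
  ba <- inject_stress(env, list(ev_b, ev_a), sc)
  expect_equal(ab$p, ba$p)

  expect_error(stress_event(0, "frost", 0.5), "frost")
})

test_that("rendering is deterministic, UAV is finer than satellite, and stress displaces features", {
  sc <- tiny_scenario(4)
  env <- sample_environment(sc, 0)
  o1 <- render_observations(sc, env, seed = 5)
  o2 <- render_observations(sc, env, seed = 5)
  expect_identical(o1, o2)
  expect_gt(prod(dim(o1$x_uav)[1:2]), prod(dim(o1$x_sat)[1:2]))

  # Monte-Carlo: mean per-zone satellite feature displacement of a
  # severity-1 drought zone exceeds 3x the render noise sd
  diffs <- vapply(seq_len(200), function(r) {
    env_r <- sample_environment(sc, r)
    ev <- stress_event(0, "drought", severity = 1)
    env_s <- inject_stress(env_r, list(ev), sc)
    obs <- render_observations(sc, env_s, list(ev), seed = r)
    zf <- zone_features(obs, sc)
    sat <- zf[, grep("^sat_", colnames(zf)), drop = FALSE]
    mean(abs(sat[1, ] - colMeans(sat[-1, , drop = FALSE])))
  }, numeric(1))
  expect_gt(mean(diffs), 3 * sc$obs$render_sd)
})

test_that("yield matches the closed-form response and its noise model", {
  sc <- field_scenario(n_zones = 2, grid_shape = c(1, 2), noise_sd = 0,
                       seed = 1)
  expect_equal(realize_yield(sc, matrix(0, 2, 3)), c(0, 0))

  # beta = (0.8, 0.6, 0.4), gamma = 0.01, U = (10, 0, 0): 8 - 1 = 7
  expect_equal(realize_yield(sc, matrix(c(10, 10, 0, 0, 0, 0), 2, 3)),
               c(7, 7), tolerance = 1e-12)

  # closed form at reference environment for arbitrary feasible U
  U <- matrix(runif(6, 0, 5), 2, 3)
  pars <- sc$true_params
  expect_equal(realize_yield(sc, U),
               drop(U %*% pars$beta) - pars$gamma * rowSums(U)^2,
               tolerance = 1e-12)

  expect_error(realize_yield(sc, matrix(-1, 2, 3)), "nonnegative")

  # Monte-Carlo: mean of noisy realizations within 3 SE of noiseless value
  scn <- field_scenario(n_zones = 1, noise_sd = 0.5, seed = 1)
  u1 <- matrix(c(10, 0, 0), 1, 3)
  noiseless <- 7
  draws <- vapply(seq_len(10000),
                  function(r) realize_yield(scn, u1, env = NULL, seed = r),
                  numeric(1))
  se <- 0.5 / sqrt(10000)
  expect_lt(abs(mean(draws) - noiseless), 3 * se)
})

test_that("expected yield is non-increasing in stress severity for every archetype", {
  sc <- tiny_scenario(4, noise_sd = 0)
  U <- matrix(5, 4, 3)
  for (type in c("drought", "nutrient_deficiency", "fungal_infection",
                 "insect_pest")) {
    means <- vapply(c(0, 0.5, 1), function(sev) {
      ys <- vapply(seq_len(100), function(r) {
        env <- sample_environment(sc, r)
        env_s <- inject_stress(env, list(stress_event(0:3, type, sev)), sc)
        mean(realize_yield(sc, U, env_s, seed = r))
      }, numeric(1))
      mean(ys)
    }, numeric(1))
    expect_true(all(diff(means) <= 1e-8),
                info = sprintf("severity monotonicity for %s", type))
  }
})

test_that("relabeling zones permutes per-zone outputs identically", {
  sc <- field_scenario(n_zones = 4, grid_shape = c(2, 2), noise_sd = 0,
                       seed = 2)
  env <- sample_environment(sc, 0)
  U <- matrix(runif(12, 0, 5), 4, 3)
  perm <- c(3L, 1L, 4L, 2L)
  env_perm <- env
  env_perm$p <- env$p[perm, ]
  expect_equal(realize_yield(sc, U[perm, ], env_perm),
               realize_yield(sc, U, env)[perm])
})
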