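# Fusion mathematics: encoding/projection, modality weighting, spatial and
# cross-modal attention, temporal aggregation, toy training.

test_that("identity encoder and projection reproduce the reshaped input", {
  params <- encoder_params(list(a = 3), d = 3, d_k = 2, seed = 1)
  params$encoders$a <- diag(3)
  params$projections$a <- diag(3)
  x <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
  out <- encode_and_project(list(a = x), params)$a
  expect_equal(unname(out[, ]), matrix(x, 4, 3), ignore_attr = TRUE)
  expect_equal(attr(out, "layout"), c(2L, 2L))

  # all-zero input -> all-zero tokens (linear, no bias)
  z <- encode_and_project(list(a = array(0, c(2, 2, 3))), params)$a
  expect_true(all(z == 0))
})

test_that("projection maps every modality to the shared dimension and checks shapes", {
  dims <- list(sat = 3, uav = 5, ground = 4, weather = 2)
  params <- encoder_params(dims, d = 7, d_k = 4, seed = 2)
  inputs <- list(sat = array(rnorm(24), c(2, 4, 3)),
                 uav = array(rnorm(60), c(3, 4, 5)),
                 ground = matrix(rnorm(8), 2, 4),
                 weather = matrix(rnorm(10), 5, 2))
  out <- encode_and_project(inputs, params)
  expect_true(all(vapply(out, ncol, integer(1)) == 7L))
  expect_equal(vapply(out, nrow, integer(1)),
               c(sat = 8L, uav = 12L, ground = 2L, weather = 5L))

  bad <- inputs; bad$uav <- array(rnorm(36), c(3, 4, 3))
  expect_error(encode_and_project(bad, params), "uav")
})

test_that("modality weights are a softmax of mean scores", {
  f <- matrix(1, 2, 2)
  w <- c(1, 1)
  # equal scores -> uniform
  expect_equal(unname(modality_weights(list(f, f, f, f), list(w, w, w, w))),
               rep(0.25, 4))
  # scores (ln 2, 0) -> (2/3, 1/3)
  f1 <- matrix(log(2), 1, 1); f2 <- matrix(0, 1, 1)
  expect_equal(unname(modality_weights(list(f1, f2), list(1, 1))),
               c(2 / 3, 1 / 3))
  # shift invariance
  base <- modality_weights(list(f1, f2), list(1, 1))
  shifted <- modality_weights(list(f1 + 5, f2 + 5), list(1, 1))
  expect_equal(base, shifted)
  expect_error(modality_weights(list(), list()), "empty")
})

test_that("spatial attention normalizes over locations and saturates on dominant logits", {
  f <- array(1, c(3, 4, 2))
  sa <- spatial_attention(f, w = c(1, 1))
  expect_equal(sa$A, matrix(1 / 12, 3, 4))

  # one dominant location -> near one-hot, attended features keep only it
  f2 <- array(0, c(2, 2, 1))
  f2[1, 1, 1] <- 50
  sa2 <- spatial_attention(f2, w = 1)
  expect_gt(sa2$A[1, 1], 1 - 1e-9)

  for (r in 1:20) {
    fr <- array(rnorm(24), c(2, 3, 4))
    expect_equal(sum(spatial_attention(fr, w = rnorm(4))$A), 1,
                 tolerance = 1e-9)
  }
  expect_error(spatial_attention(matrix(1, 2, 2), w = 1), "array")
})

test_that("temporal aggregation honors the recurrent and transformer contracts", {
  params <- encoder_params(list(a = 3), d = 4, d_k = 2, seed = 3)

  # zero recurrent weights -> zero output
  pz <- params
  pz$recurrent <- list(w_h = matrix(0, 4, 4), u_h = matrix(0, 4, 4),
                       b_h = rep(0, 4))
  expect_equal(temporal_aggregate(matrix(rnorm(20), 5, 4), pz,
                                  mode = "recurrent"), rep(0, 4))

  # single-token transformer returns the value projection
  x1 <- matrix(rnorm(4), 1, 4)
  expect_equal(temporal_aggregate(x1, params, positions = FALSE),
               drop(x1 %*% params$w_v))

  # recurrent output depends only on the realized prefix
  x <- matrix(rnorm(12), 3, 4)
  expect_equal(temporal_aggregate(x, params, mode = "recurrent"),
               temporal_aggregate(rbind(x), params, mode = "recurrent"))

  # with positions, permuting the sequence changes the output
  xs <- matrix(rnorm(16), 4, 4)
  perm <- c(3, 1, 4, 2)
  expect_false(isTRUE(all.equal(
    temporal_aggregate(xs, params),
    temporal_aggregate(xs[perm, ], params))))

  expect_error(temporal_aggregate(matrix(0, 0, 4), params), "nonempty")
})

test_that("cross-modal attention matches the brute-force oracle", {
  set.seed(6)
  params <- encoder_params(list(a = 4, b = 4), d = 6, d_k = 3, seed = 6)
  for (r in 1:10) {
    n1 <- sample(1:8, 1); n2 <- sample(1:8, 1)
    f1 <- matrix(rnorm(n1 * 6), n1, 6)
    f2 <- matrix(rnorm(n2 * 6), n2, 6)
    got <- cross_modal_attention(f1, f2, params)
    want <- brute_force_attention(f1 %*% params$w_q, f2 %*% params$w_k,
                                  f2 %*% params$w_v, d_k = params$d_k)
    expect_equal(got$C, want$C, tolerance = 1e-10)
    expect_equal(got$f_cross, want$out, tolerance = 1e-10)
    expect_equal(rowSums(got$C), rep(1, n1), tolerance = 1e-9)
  }
})

test_that("fusion satisfies the residual contract and single-key limits", {
  params <- encoder_params(list(a = 2, b = 2), d = 4, d_k = 4, seed = 7)

  # two identical single-token modalities with identity projections:
  # attending over one key returns that token's value
  pid <- params
  pid$w_q <- diag(4); pid$w_k <- diag(4); pid$w_v <- diag(4)
  tok <- matrix(rnorm(4), 1, 4)
  fr <- cross_modal_fuse(list(a = tok, b = tok), pid)
  expect_equal(fr$pairwise[["a->b"]]$f_cross, tok)

  # residual: F_final - F_fused == sum of mean-pooled modality features
  for (r in 1:20) {
    f1 <- matrix(rnorm(12), 3, 4)
    f2 <- matrix(rnorm(20), 5, 4)
    fu <- cross_modal_fuse(list(a = f1, b = f2), params)
    expect_equal(fu$f_final - fu$f_fused, fu$residual_sum,
                 tolerance = 1e-12)
    expect_equal(fu$residual_sum,
                 matrix(colMeans(f1) + colMeans(f2), 1), tolerance = 1e-12)
    for (cm in fu$modality_attention)
      expect_equal(rowSums(cm), 1, tolerance = 1e-9)
  }

  expect_error(cross_modal_fuse(list(a = matrix(0, 1, 4)), params),
               "at least 2")
})

test_that("attention is equivariant under key/value permutation and never produces NaN", {
  params <- encoder_params(list(a = 3, b = 3), d = 5, d_k = 3, seed = 8)
  for (r in 1:25) {
    f1 <- matrix(rnorm(10, sd = 3), 2, 5)
    f2 <- matrix(rnorm(30, sd = 3), 6, 5)
    perm <- sample(6)
    a <- cross_modal_attention(f1, f2, params)
    b <- cross_modal_attention(f1, f2[perm, ], params)
    expect_equal(b$C, a$C[, perm, drop = FALSE], tolerance = 1e-12)
    expect_equal(b$f_cross, a$f_cross, tolerance = 1e-12)
    expect_false(any(!is.finite(a$C)))
  }
})

test_that("toy detector training is deterministic and inert at zero learning rate", {
  sc <- tiny_scenario(16, seed = 11)
  frozen <- train_toy_detector(sc, epochs = 5, lr = 0, seed = 3)
  expect_equal(frozen$params$theta, rep(0, 4))
  expect_equal(frozen$params$w_head, rep(0, 16))

  a <- train_toy_detector(sc, epochs = 40, lr = 0.5, seed = 3)
  b <- train_toy_detector(sc, epochs = 40, lr = 0.5, seed = 3)
  expect_identical(a$loss, b$loss)
  expect_identical(a$params$w_head, b$params$w_head)
  expect_true(all(diff(a$loss) <= 1e-6))
})

test_that("toy detector separates strongly stressed zones on held-out data", {
  sc <- tiny_scenario(16, seed = 11)
  fit <- train_toy_detector(sc, epochs = 300, lr = 0.5, seed = 3)
  expect_gte(fit$result$metrics$f1, 0.9)
})
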