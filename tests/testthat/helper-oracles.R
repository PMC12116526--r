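# Independent oracles and shared fixtures for the suite.

# Brute-force scaled dot-product attention: explicit double loop, no matrix
# algebra shared with the implementation.
brute_force_attention <- function(q, k, v, d_k = ncol(k)) {
  n_q <- nrow(q); n_k <- nrow(k)
  C <- matrix(NA_real_, n_q, n_k)
  for (i in seq_len(n_q)) {
    logits <- numeric(n_k)
    for (j in seq_len(n_k)) {
      acc <- 0
      for (l in seq_len(ncol(q))) acc <- acc + q[i, l] * k[j, l]
      logits[j] <- acc / sqrt(d_k)
    }
    e <- exp(logits - max(logits))
    C[i, ] <- e / sum(e)
  }
  out <- matrix(0, n_q, ncol(v))
  for (i in seq_len(n_q)) {
    for (j in seq_len(n_k)) out[i, ] <- out[i, ] + C[i, j] * v[j, ]
  }
  list(C = C, out = out)
}

# Multivariate normal log-likelihood, written out directly (oracle for the
# score/likelihood monotone-equivalence check).
mvn_loglik <- function(x, mu, sigma) {
  d <- length(mu)
  si <- solve(sigma)
  dev <- sweep(as.matrix(x), 2L, mu)
  q <- rowSums((dev %*% si) * dev)
  -0.5 * (d * log(2 * pi) + determinant(sigma, logarithm = TRUE)$modulus + q)
}

# Small default scenario used across tests.
tiny_scenario <- function(n = 4, seed = 7, noise_sd = 0.5, ...) {
  rows <- floor(sqrt(n)); cols <- n / rows
  stopifnot(rows * cols == n)
  field_scenario(n_zones = n, grid_shape = c(rows, cols),
                 noise_sd = noise_sd, seed = seed, ...)
}

# Random objective parameters on the unit scale (grid-oracle friendly).
random_params <- function() {
  objective_params(beta = runif(3, 0.3, 1.0), gamma = runif(1, 0.5, 1.5),
                   costs = runif(3, 0, 0.2), env_costs = runif(3, 0, 0.1),
                   lambda1 = runif(1, 0, 1), lambda2 = runif(1, 0, 1))
}

# Documented Lipschitz bound on the objective gradient over the feasible
# box (used to convert a grid step into an objective gap allowance).
objective_lipschitz <- function(params, budgets) {
  m <- params$beta - params$lambda1 * params$costs -
    params$lambda2 * params$env_costs
  3 * (max(abs(m)) + 2 * params$gamma * sum(budgets))
}
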