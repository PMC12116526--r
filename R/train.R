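# Toy end-to-end detector: fusion front-end with trainable modality mixing
# weights and a logistic head, trained by full-batch gradient descent on
# binary stress labels generated by the field simulator.

#' Generate labelled per-zone training data from the simulator
#'
#' Draws `n_reps` independent field snapshots; in each, a balanced subset of
#' zones is stressed at the given severity, observations are rendered, and
#' per-zone modality feature blocks are extracted (satellite / UAV channel
#' means, sensor vector, field-level weather summary replicated per zone).
#'
#' @param scenario a [field_scenario].
#' @param n_reps number of independent snapshots (default 8).
#' @param severity stress severity in [0, 1] (default 1).
#' @param stress_type stress archetype injected (default `"drought"`).
#' @param seed integer seed.
#' @return list with `features` (named list of per-modality matrices, rows
#'   = zone-snapshots), `labels` (logical), and `rep` (snapshot index per
#'   row, for grouped train/test splits).
#' @export
make_labelled_zones <- function(scenario, n_reps = 8, severity = 1,
                                stress_type = "drought", seed = 1L) {
  stopifnot(inherits(scenario, "field_scenario"))
  n <- scenario$n_zones
  feats <- list(sat = NULL, uav = NULL, ground = NULL, weather = NULL)
  labels <- logical(0)
  rep_id <- integer(0)
  for (r in seq_len(n_reps)) {
    env <- sample_environment(scenario, t = r - 1L)
    stressed <- which((seq_len(n) - 1L + r) %% 2L == 0L) - 1L
    ev <- stress_event(stressed, stress_type, severity)
    env_s <- inject_stress(env, list(ev), scenario)
    obs <- render_observations(scenario, env_s, list(ev),
                               seed = derive_seed(seed, 5L, r))
    zf <- zone_features(obs, scenario)
    sat_cols <- grep("^sat_", colnames(zf))
    uav_cols <- grep("^uav_", colnames(zf))
    sens_cols <- grep("^sens_", colnames(zf))
    wx <- matrix(colMeans(obs$x_weather), n, ncol(obs$x_weather),
                 byrow = TRUE)
    feats$sat <- rbind(feats$sat, zf[, sat_cols, drop = FALSE])
    feats$uav <- rbind(feats$uav, zf[, uav_cols, drop = FALSE])
    feats$ground <- rbind(feats$ground, zf[, sens_cols, drop = FALSE])
    feats$weather <- rbind(feats$weather, wx)
    labels <- c(labels, (seq_len(n) - 1L) %in% stressed)
    rep_id <- c(rep_id, rep(r, n))
  }
  list(features = feats, labels = labels, rep = rep_id)
}

#' Train the toy stress detector
#'
#' Front-end: each zone's per-modality feature block is projected into the
#' shared latent space with the seeded (fixed) fusion projections; the
#' per-zone representation is the softmax-weighted modality mixture
#' `z_i = sum_m w_m(theta) g_{m,i}`. A logistic head on `z` predicts the
#' stress label. The modality mixing scores `theta` and the head
#' `(w_head, b)` are trained jointly by full-batch gradient descent on the
#' cross-entropy loss with analytic gradients (including the softmax
#' Jacobian for `theta`). Deterministic given `seed`; snapshots are split
#' by repetition into training and held-out halves.
#'
#' @param scenario a [field_scenario].
#' @param epochs gradient steps (default 300).
#' @param lr learning rate (default 0.5); `lr = 0` leaves all parameters at
#'   their initialization.
#' @param seed integer seed.
#' @param severity,stress_type,n_reps forwarded to [make_labelled_zones()].
#' @param d latent dimension of the front-end (default 16).
#' @return list with `params` (`theta`, `w_head`, `b`, the fixed
#'   projections, final modality `weights`), `loss` (per-epoch training
#'   loss) and `result` (a `detection_result` on the held-out half,
#'   threshold 0.5 on the predicted probability).
#' @export
train_toy_detector <- function(scenario, epochs = 300, lr = 0.5, seed = 1L,
                               severity = 1, stress_type = "drought",
                               n_reps = 8, d = 16) {
  data <- make_labelled_zones(scenario, n_reps = n_reps,
                              severity = severity,
                              stress_type = stress_type, seed = seed)
  mods <- names(data$features)
  dims <- lapply(data$features, ncol)
  proj <- with_seed(derive_seed(seed, 5L, 999L), {
    lapply(dims, function(d_in)
      matrix(stats::rnorm(d_in * d, sd = 1 / sqrt(d_in)), d_in, d))
  })
  # standardize inputs per column (fixed transform, fit on all data)
  feats <- lapply(data$features, function(m) {
    mu <- colMeans(m); sdv <- pmax(apply(m, 2L, stats::sd), 1e-8)
    sweep(sweep(m, 2L, mu), 2L, sdv, "/")
  })
  g <- lapply(mods, function(m) feats[[m]] %*% proj[[m]])
  names(g) <- mods

  train_idx <- data$rep <= max(data$rep) / 2
  y <- as.numeric(data$labels)

  theta <- rep(0, length(mods))
  w_head <- rep(0, d)
  b <- 0
  losses <- numeric(0)

  g_tr <- lapply(g, function(m) m[train_idx, , drop = FALSE])
  y_tr <- y[train_idx]
  n_tr <- sum(train_idx)

  for (ep in seq_len(epochs)) {
    w_mod <- softmax(theta)
    z <- Reduce(`+`, Map(function(gm, wm) wm * gm, g_tr, as.list(w_mod)))
    a <- drop(z %*% w_head) + b
    p <- stats::plogis(a)
    eps <- 1e-12
    loss <- -mean(y_tr * log(p + eps) + (1 - y_tr) * log(1 - p + eps))
    if (!is.finite(loss))
      af_stop("training diverged (loss is not finite); lower lr",
              class = "agrifusion_training_error")
    losses <- c(losses, loss)
    if (lr == 0) next
    delta <- (p - y_tr) / n_tr
    grad_w <- drop(t(z) %*% delta)
    grad_b <- sum(delta)
    # dL/dw_m before the softmax Jacobian
    dz <- outer(delta, w_head)          # n x d
    grad_wmod <- vapply(mods, function(m) sum(dz * g_tr[[m]]), numeric(1))
    grad_theta <- w_mod * (grad_wmod - sum(w_mod * grad_wmod))
    theta <- theta - lr * grad_theta
    w_head <- w_head - lr * grad_w
    b <- b - lr * grad_b
  }

  w_mod <- softmax(theta)
  z_all <- Reduce(`+`, Map(function(gm, wm) wm * gm, g, as.list(w_mod)))
  p_all <- stats::plogis(drop(z_all %*% w_head) + b)
  held <- !train_idx
  result <- classify_and_evaluate(p_all[held], tau = 0.5,
                                  truth = data$labels[held])
  list(params = list(theta = theta, w_head = w_head, b = b,
                     projections = proj,
                     weights = stats::setNames(w_mod, mods)),
       loss = losses, result = result)
}
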