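# Closed-loop feedback control of resource allocations: deviation
# computation, additive allocation and priority updates, and a harness that
# runs the loop against the field simulator.

#' Controller state
#'
#' @param alpha global learning rate (used for any resource without a
#'   specific rate).
#' @param alpha_r length-3 per-resource learning rates
#'   (water, fertilizer, pesticide), in resource units per yield unit.
#'   Defaults are deliberately conservative.
#' @param beta_vec vector mapping environmental deviations to priority
#'   adjustments (one entry per environmental variable; negative entries
#'   make a worse-than-predicted variable raise the zone's priority).
#' @return an object of class `controller_state`.
#' @export
controller_state <- function(alpha = 0.05,
                             alpha_r = c(0.10, 0.05, 0.01),
                             beta_vec = c(-0.5, 0, -0.5, -0.5)) {
  check_scalar(alpha, "alpha", function(v) v >= 0, "nonnegative")
  if (length(alpha_r) != 3L || any(alpha_r < 0) || any(!is.finite(alpha_r)))
    af_stop("field 'alpha_r' must be three nonnegative rates",
            class = "agrifusion_validation_error")
  if (any(!is.finite(beta_vec)))
    af_stop("field 'beta_vec' must be finite",
            class = "agrifusion_validation_error")
  structure(list(alpha = alpha, alpha_r = as.double(alpha_r),
                 beta_vec = as.double(beta_vec)),
            class = "controller_state")
}

#' Observed-minus-predicted deviations
#'
#' \deqn{\Delta Y = Y^{obs} - \hat y, \qquad \Delta p = p^{obs} - p^{pred}.}
#' Positive yield deviations indicate the zone responded better than
#' predicted (more resources could pay off); negative ones suggest
#' over-application.
#'
#' @param y_obs,y_hat observed and predicted yield vectors.
#' @param p_obs,p_pred observed and predicted environmental matrices
#'   (optional; both or neither).
#' @return list with `dY` and (if environmental inputs given) `dp`.
#' @export
compute_deviations <- function(y_obs, y_hat, p_obs = NULL, p_pred = NULL) {
  if (length(y_obs) != length(y_hat))
    af_stop("y_obs and y_hat must have the same length",
            class = "agrifusion_validation_error")
  out <- list(dY = y_obs - y_hat)
  if (!is.null(p_obs) || !is.null(p_pred)) {
    p_obs <- as.matrix(p_obs); p_pred <- as.matrix(p_pred)
    if (!all(dim(p_obs) == dim(p_pred)))
      af_stop("p_obs and p_pred must have the same shape",
              class = "agrifusion_validation_error")
    out$dp <- p_obs - p_pred
  }
  out
}

#' Update allocations from yield deviations
#'
#' Applies the additive rule
#' \eqn{u_i^{(r)}(t+1) = u_i^{(r)}(t) + \alpha_r \Delta Y_i(t)} per
#' resource, then restores feasibility: entries are clipped to
#' `[0, caps]` and any resource column exceeding its budget is brought
#' back by [cap_and_renormalize()] (shares proportional to the updated
#' allocation). A feasible allocation with zero deviations is returned
#' unchanged, bit for bit.
#'
#' @param U current `n x 3` feasible allocation.
#' @param dY yield deviation vector.
#' @param state a [controller_state].
#' @param caps `n x 3` cap matrix (length-3 recycled).
#' @param budgets length-3 budgets.
#' @return updated feasible allocation matrix.
#' @export
update_allocation <- function(U, dY, state, caps, budgets) {
  stopifnot(inherits(state, "controller_state"))
  U <- as.matrix(U)
  if (length(dY) != nrow(U))
    af_stop("dY length must match the number of zones",
            class = "agrifusion_validation_error")
  caps <- expand_caps_inf(caps, nrow(U))
  upd <- U + outer(dY, state$alpha_r)
  if (identical(max(abs(upd - U)), 0)) return(U)
  upd <- pmin(pmax(upd, 0), caps)
  for (k in 1:3) {
    if (sum(upd[, k]) > budgets[k]) {
      upd[, k] <- cap_and_renormalize(upd[, k], caps[, k], budgets[k],
                                      r = upd[, k])
    }
  }
  colnames(upd) <- c("water", "fertilizer", "pesticide")
  upd
}

#' Update priority scores from environmental deviations
#'
#' \deqn{r_i(t+1) = r_i(t) + \beta^\top \Delta p_i(t).} Additive, so two
#' successive deviation batches are equivalent to their sum.
#'
#' @param r current priority vector.
#' @param dp `n x d_p` environmental deviation matrix.
#' @param beta_vec d_p-vector of mapping weights.
#' @return updated priority vector.
#' @export
update_priorities <- function(r, dp, beta_vec) {
  dp <- as.matrix(dp)
  if (nrow(dp) != length(r) || ncol(dp) != length(beta_vec))
    af_stop("priority update shapes disagree",
            class = "agrifusion_validation_error")
  r + drop(dp %*% beta_vec)
}

#' Perfect-model predictor
#'
#' The default predictor for controller runs: predicts yield with the
#' scenario's own noiseless response (including the environmental
#' modifier) and the environmental state exactly. Under it and a noiseless
#' scenario the loop sits at a fixed point.
#'
#' @param scenario a [field_scenario].
#' @return function `(U, env) -> list(y_hat, p_pred)`.
#' @export
perfect_predictor <- function(scenario) {
  force(scenario)
  function(U, env) {
    base <- drop(as_allocation_matrix(U, scenario$n_zones) %*%
                   scenario$true_params$beta) -
      scenario$true_params$gamma * rowSums(as_allocation_matrix(
        U, scenario$n_zones))^2
    list(y_hat = base + yield_env_modifier(scenario, env),
         p_pred = env$p)
  }
}

#' Run the closed feedback loop against the simulator
#'
#' At each step `t` in `[0, T)`: sample the environment (applying any
#' active stress events), realize yields under the current allocation,
#' compute observed-minus-predicted deviations, update the allocation
#' (additive rule + feasibility projection) and the priority scores, and
#' log everything. Deterministic given `seed`.
#'
#' @param scenario a [field_scenario].
#' @param initial_plan starting allocation (`n x 3` matrix or
#'   [allocation_plan]).
#' @param state a [controller_state].
#' @param T_steps number of steps (`>= 1`).
#' @param predictor function `(U, env) -> list(y_hat, p_pred)`; default
#'   [perfect_predictor()].
#' @param seed integer seed for yield noise.
#' @param events list of [stress_event]s applied when active.
#' @param reallocate_every if set, every that-many steps the allocation is
#'   recomputed from the current priorities via proportional allocation
#'   (otherwise priorities are tracked but allocations evolve only through
#'   the additive update).
#' @return an object of class `trajectory`: `records` (long data.frame with
#'   columns `t, zone_id, resource, u, y_obs, y_hat, dY, r`), `history`
#'   (per-step list), and `abs_dY` (per-step median absolute yield
#'   deviation).
#' @export
run_closed_loop <- function(scenario, initial_plan, state, T_steps,
                            predictor = NULL, seed = 1L, events = list(),
                            reallocate_every = NULL) {
  stopifnot(inherits(scenario, "field_scenario"),
            inherits(state, "controller_state"))
  check_scalar(T_steps, "T_steps", function(v) v >= 1 && v == round(v),
               "positive integer")
  if (is.null(predictor)) predictor <- perfect_predictor(scenario)
  U <- as_allocation_matrix(initial_plan, scenario$n_zones)
  caps <- scenario$caps
  budgets <- scenario$budgets
  n <- scenario$n_zones
  r <- rep(0, n)
  env <- NULL
  history <- vector("list", T_steps)
  recs <- list()
  abs_dY <- numeric(T_steps)
  for (t in seq_len(T_steps) - 1L) {
    env <- sample_environment(scenario, t, env)
    act <- active_events(events, t)
    if (length(act)) env <- inject_stress(env, act, scenario)
    y_obs <- realize_yield(scenario, U, env, seed = derive_seed(seed, 6L, t))
    pred <- predictor(U, env)
    dev <- compute_deviations(y_obs, pred$y_hat, env$p, pred$p_pred)
    if (any(!is.finite(dev$dY)) || any(!is.finite(U)))
      af_stop(sprintf(
        "controller state not finite at t = %d; reduce alpha_r (currently %s)",
        t, paste(state$alpha_r, collapse = ", ")),
        class = "agrifusion_control_error")
    history[[t + 1L]] <- list(t = t, U = U, y_obs = y_obs,
                              y_hat = pred$y_hat, dY = dev$dY,
                              dp = dev$dp, r = r)
    abs_dY[t + 1L] <- stats::median(abs(dev$dY))
    recs[[t + 1L]] <- data.frame(
      t = t,
      zone_id = rep(seq_len(n) - 1L, times = 3L),
      resource = rep(c("water", "fertilizer", "pesticide"), each = n),
      u = as.vector(U),
      y_obs = rep(y_obs, times = 3L),
      y_hat = rep(pred$y_hat, times = 3L),
      dY = rep(dev$dY, times = 3L),
      r = rep(r, times = 3L))
    U <- update_allocation(U, dev$dY, state, caps, budgets)
    r <- update_priorities(r, dev$dp, state$beta_vec)
    if (!is.null(reallocate_every) && (t + 1L) %% reallocate_every == 0L &&
        any(r > 0)) {
      for (k in 1:3) {
        u_k <- proportional_allocation(r, budgets[k], fallback = "uniform")
        U[, k] <- cap_and_renormalize(u_k, caps[, k], budgets[k], r = r)
      }
    }
  }
  structure(list(records = do.call(rbind, recs), history = history,
                 abs_dY = abs_dY, final_U = U, final_r = r),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  ts <- unique(x$records$t)
  cat(sprintf("Closed-loop trajectory: %d steps, %d zones\n",
              length(ts), length(unique(x$records$zone_id))))
  cat(sprintf("  median |dY|: first %.4g, last %.4g\n",
              x$abs_dY[1L], x$abs_dY[length(x$abs_dY)]))
  invisible(x)
}
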