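# Multi-objective resource allocation: objective evaluation, analytic
# unconstrained optimum, projected-gradient constrained solver with a KKT
# certificate, a brute-force grid oracle, and a weighted-sum Pareto sweep.
#
# The scalarized objective O(U) = Y(U) - lambda1 C(U) - lambda2 E(U) is
# concave in U (linear terms minus a positive-semidefinite quadratic), so
# any feasible first-order stationary point is globally optimal; the
# fixed-point residual of the projection operator certifies optimality.

# Net margins per resource: m_k = beta_k - lambda1 c_k - lambda2 e_k.
net_margins <- function(params) {
  stopifnot(inherits(params, "objective_params"))
  params$beta - params$lambda1 * params$costs -
    params$lambda2 * params$env_costs
}

#' Evaluate the management objective
#'
#' \deqn{O(U) = Y(U) - \lambda_1 C(U) - \lambda_2 E(U)} with
#' \eqn{Y = \sum_i (\beta^\top u_i - \gamma s_i^2)}, \eqn{s_i} the zone's
#' total input, and linear cost and environmental terms.
#'
#' @param U `n x 3` nonnegative allocation matrix (a length-3 vector is a
#'   single zone).
#' @param params an [objective_params].
#' @return list with components `O`, `Y`, `C`, `E`.
#' @export
objective_value <- function(U, params) {
  stopifnot(inherits(params, "objective_params"))
  if (is.vector(U) && length(U) == 3L) U <- matrix(U, nrow = 1L)
  U <- as.matrix(U)
  if (ncol(U) != 3L || any(!is.finite(U)))
    af_stop("allocation must be a finite n x 3 matrix",
            class = "agrifusion_validation_error")
  if (any(U < 0))
    af_stop("allocation entries must be nonnegative",
            class = "agrifusion_validation_error")
  y <- sum(U %*% params$beta) - params$gamma * sum(rowSums(U)^2)
  cost <- sum(U %*% params$costs)
  env <- sum(U %*% params$env_costs)
  list(O = y - params$lambda1 * cost - params$lambda2 * env,
       Y = y, C = cost, E = env)
}

# Gradient of O with respect to U (n x 3): dO/du_ik = m_k - 2 gamma s_i.
objective_gradient <- function(U, params) {
  m <- net_margins(params)
  s <- rowSums(U)
  matrix(m, nrow(U), 3L, byrow = TRUE) - 2 * params$gamma * s
}

#' Construct an allocation plan
#'
#' @param U `n x 3` allocation matrix.
#' @param feasible logical feasibility flag.
#' @param binding character vector naming active constraints.
#' @param diagnostics optional solver diagnostics.
#' @return an object of class `allocation_plan`.
#' @export
allocation_plan <- function(U, feasible = TRUE, binding = character(0),
                            diagnostics = list()) {
  U <- as.matrix(U)
  colnames(U) <- c("water", "fertilizer", "pesticide")
  structure(list(U = U, feasible = feasible, binding = binding,
                 diagnostics = diagnostics),
            class = "allocation_plan")
}

#' @export
print.allocation_plan <- function(x, ...) {
  cat(sprintf("Allocation plan: %d zones, %s\n", nrow(x$U),
              if (x$feasible) "feasible" else "INFEASIBLE"))
  cat(sprintf("  column totals (w/f/p): %s\n",
              paste(signif(colSums(x$U), 6), collapse = " / ")))
  if (length(x$binding))
    cat("  binding:", paste(x$binding, collapse = ", "), "\n")
  if (!is.null(x$diagnostics$kkt_residual))
    cat(sprintf("  KKT residual: %.3g (iterations: %d)\n",
                x$diagnostics$kkt_residual, x$diagnostics$iterations))
  invisible(x)
}

#' Closed-form unconstrained optimum
#'
#' Without budgets or caps the objective separates by zone. With net margin
#' \eqn{m_k = \beta_k - \lambda_1 c_k - \lambda_2 e_k}, the per-zone
#' optimum puts all mass on the argmax-margin resource (lowest index on
#' ties) with total \eqn{s^* = m_{max} / (2\gamma)}, achieving
#' \eqn{m_{max}^2 / (4\gamma)} per zone; if no margin is positive the
#' optimum is the zero allocation. (Stationarity of
#' \eqn{m_{max} s - \gamma s^2}; concentrating on the best margin dominates
#' any split with equal total.)
#'
#' @param params an [objective_params].
#' @param n_zones number of zones (default 1).
#' @return an [allocation_plan] with the optimum recorded in
#'   `diagnostics$objective`.
#' @export
analytic_unconstrained_optimum <- function(params, n_zones = 1L) {
  m <- net_margins(params)
  U <- matrix(0, n_zones, 3L)
  if (max(m) > 0) {
    k <- which.max(m)   # lowest index wins ties
    U[, k] <- m[k] / (2 * params$gamma)
  }
  allocation_plan(U, feasible = TRUE,
                  diagnostics = list(objective = objective_value(U, params)$O,
                                     margins = m))
}

# Euclidean projection of v onto {0 <= u <= caps, sum(u) <= budget}
# (capped simplex with inequality): clip first; if the clipped point is
# within budget it is the projection, otherwise bisect the shift theta so
# that sum(clip(v - theta, 0, caps)) == budget.
project_capped_simplex <- function(v, caps, budget) {
  u <- clip(v, 0, caps)
  if (sum(u) <= budget + 1e-15 * max(1, budget)) return(u)
  if (budget <= 0) return(rep(0, length(v)))
  lo <- 0
  hi <- max(v)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    s <- sum(clip(v - mid, 0, caps))
    if (s > budget) lo <- mid else hi <- mid
    if (hi - lo < 1e-15 * max(1, hi)) break
  }
  u <- clip(v - hi, 0, caps)
  # exact budget up to numerical tolerance; rescale the residual slack onto
  # unsaturated coordinates
  u
}

# Project a full allocation onto the feasible set (per-resource columns are
# independent).
project_allocation <- function(U, caps, budgets) {
  for (k in 1:3) {
    U[, k] <- project_capped_simplex(U[, k], caps[, k], budgets[k])
  }
  U
}

#' KKT fixed-point residual of an allocation
#'
#' For the concave objective over the convex feasible set
#' `{U >= 0, U <= caps, column sums <= budgets}`, `U` is globally optimal
#' iff it is a fixed point of the projected-gradient map; the residual is
#' `max | U - Proj(U + grad O(U)) |`.
#'
#' @param U allocation matrix or [allocation_plan].
#' @param params an [objective_params].
#' @param budgets length-3 budget vector.
#' @param caps `n x 3` cap matrix (length-3 vector recycled).
#' @return the residual (0 at the optimum).
#' @export
kkt_residual <- function(U, params, budgets, caps) {
  if (inherits(U, "allocation_plan")) U <- U$U
  caps <- expand_caps(caps, nrow(U))
  g <- objective_gradient(U, params)
  max(abs(U - project_allocation(U + g, caps, budgets)))
}

#' Solve the constrained allocation problem
#'
#' Maximizes the concave objective over
#' `{U >= 0, U <= caps, column sums <= budgets}` by monotone accelerated
#' projected-gradient ascent: Nesterov extrapolation with a restart
#' whenever the extrapolated step fails to increase the objective (the
#' plain projected step with step size `1/L`, `L = 6 gamma` the gradient's
#' Lipschitz constant, is then guaranteed ascent). Projection onto the
#' feasible set is exact per resource (clip to the box, then bisection on
#' the simplex shift). Convergence is declared when the projected-gradient
#' fixed-point residual drops below `tol`; the result carries a KKT
#' certificate (see [kkt_residual()]).
#'
#' @param params an [objective_params].
#' @param budgets length-3 budgets (may be `Inf`).
#' @param caps per-zone caps, length-3 vector or `n x 3` matrix (may be
#'   `Inf`).
#' @param n_zones number of zones.
#' @param tol fixed-point residual tolerance (default 1e-10).
#' @param max_iter iteration cap (default 10000).
#' @param U0 optional feasible start (default 0).
#' @return an [allocation_plan]; `diagnostics` holds the objective, the
#'   iteration count, the per-iteration objective trace (non-decreasing),
#'   the KKT residual and a `converged` flag.
#' @export
solve_constrained <- function(params, budgets, caps, n_zones,
                              tol = 1e-10, max_iter = 10000L, U0 = NULL) {
  stopifnot(inherits(params, "objective_params"))
  if (any(budgets < 0))
    af_stop("field 'budgets' must be nonnegative",
            class = "agrifusion_validation_error")
  caps <- expand_caps_inf(caps, n_zones)
  budgets <- as.double(budgets)
  U <- if (is.null(U0)) matrix(0, n_zones, 3L)
       else project_allocation(as.matrix(U0), caps, budgets)
  step <- 1 / (6 * params$gamma)   # 1/L, L = ||2 gamma 11^T|| per zone
  obj <- objective_value(U, params)$O
  trace <- obj
  v <- U            # extrapolation point
  t_acc <- 1
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    u_new <- project_allocation(v + step * objective_gradient(v, params),
                                caps, budgets)
    obj_new <- objective_value(u_new, params)$O
    if (obj_new < obj) {
      # restart: plain projected-gradient step from U is monotone
      u_new <- project_allocation(U + step * objective_gradient(U, params),
                                  caps, budgets)
      obj_new <- objective_value(u_new, params)$O
      t_acc <- 1
    }
    t_new <- (1 + sqrt(1 + 4 * t_acc^2)) / 2
    v <- u_new + ((t_acc - 1) / t_new) * (u_new - U)
    resid <- max(abs(u_new - U))
    U <- u_new
    obj <- obj_new
    trace <- c(trace, obj)
    t_acc <- t_new
    if (resid < tol &&
        kkt_residual(U, params, budgets, caps) < max(tol * 100, 1e-8)) {
      converged <- TRUE
      break
    }
  }
  res <- kkt_residual(U, params, budgets, caps)
  binding <- character(0)
  for (k in 1:3) {
    if (is.finite(budgets[k]) &&
        sum(U[, k]) >= budgets[k] - 1e-7 * max(1, budgets[k]))
      binding <- c(binding, paste0("budget_", colnames(caps)[k]))
    if (any(is.finite(caps[, k]) & U[, k] >= caps[, k] - 1e-9))
      binding <- c(binding, paste0("cap_", colnames(caps)[k]))
  }
  if (!converged)
    warning("solver hit max_iter before reaching tolerance; plan flagged")
  allocation_plan(U, feasible = TRUE, binding = binding,
                  diagnostics = list(objective = obj, iterations = iter,
                                     trace = trace, kkt_residual = res,
                                     converged = converged))
}

# expand_caps that tolerates Inf entries.
expand_caps_inf <- function(caps, n_zones) {
  if (is.matrix(caps)) {
    stopifnot(nrow(caps) == n_zones, ncol(caps) == 3L)
  } else {
    stopifnot(length(caps) == 3L)
    caps <- matrix(rep(as.double(caps), each = n_zones), nrow = n_zones)
  }
  if (any(caps < 0))
    af_stop("field 'caps' must be nonnegative",
            class = "agrifusion_validation_error")
  colnames(caps) <- c("water", "fertilizer", "pesticide")
  caps
}

#' Brute-force grid search oracle
#'
#' Exhaustive search of the constrained allocation problem on a regular
#' grid of step `step`, for 1 or 2 zones. For two zones, the second zone's
#' best objective within any residual-budget box is precomputed with a
#' running-maximum table so the search stays polynomial. Independent of the
#' projected-gradient solver; intended as a testing oracle.
#'
#' @param params an [objective_params].
#' @param budgets length-3 finite budgets.
#' @param caps length-3 caps (or `n x 3` matrix).
#' @param n_zones 1 or 2.
#' @param step grid step (default 0.05).
#' @return list with the best grid objective `O` and the grid step.
#' @export
grid_search_allocation <- function(params, budgets, caps, n_zones,
                                   step = 0.05) {
  stopifnot(n_zones %in% c(1L, 2L), all(is.finite(budgets)))
  caps <- expand_caps_inf(caps, n_zones)
  levels_for <- function(k) seq(0, budgets[k], by = step)
  lev <- lapply(1:3, levels_for)
  grid <- expand.grid(w = lev[[1]], f = lev[[2]], p = lev[[3]])
  zone_obj <- function(zone) {
    m <- net_margins(params)
    u <- as.matrix(grid)
    ok <- u[, 1] <= caps[zone, 1] & u[, 2] <= caps[zone, 2] &
      u[, 3] <= caps[zone, 3]
    val <- drop(u %*% m) - params$gamma * rowSums(u)^2
    val[!ok] <- -Inf
    array(val, dim = vapply(lev, length, integer(1)))
  }
  f1 <- zone_obj(1L)
  if (n_zones == 1L) return(list(O = max(f1), step = step))
  f2 <- zone_obj(2L)
  # running max over the <= box: cumulative max along each dimension
  m2 <- f2
  for (dimn in 1:3) {
    m2 <- apply(m2, setdiff(1:3, dimn), cummax)
    # apply permutes dims; rotate back
    m2 <- aperm(m2, order(c(dimn, setdiff(1:3, dimn))))
  }
  best <- -Inf
  nl <- vapply(lev, length, integer(1))
  idx <- which(is.finite(f1), arr.ind = TRUE)
  vals1 <- f1[idx]
  # remaining-budget index for zone 2: budget_k - u1_k, floor to grid
  rem <- function(k, i) {
    pmax(0L, pmin(nl[k], floor((budgets[k] - lev[[k]][i]) / step + 1e-9) + 1L))
  }
  r1 <- rem(1L, idx[, 1]); r2 <- rem(2L, idx[, 2]); r3 <- rem(3L, idx[, 3])
  ok <- r1 >= 1L & r2 >= 1L & r3 >= 1L
  if (any(ok)) {
    lin <- (r3[ok] - 1L) * nl[1] * nl[2] + (r2[ok] - 1L) * nl[1] + r1[ok]
    tot <- vals1[ok] + m2[lin]
    best <- max(tot)
  }
  # allow zone 2 to be all-zero even if some rem index was 0 (cannot happen
  # since grids start at 0), and compare with zone1-only/zero plans
  best <- max(best, max(vals1), 0)
  list(O = best, step = step)
}

#' Weighted-sum Pareto sweep
#'
#' Traces the yield / cost / environmental-impact trade-off surface by
#' solving the constrained problem over a grid of `(lambda1, lambda2)`
#' scalarization weights.
#'
#' @param params an [objective_params] (its lambdas are overridden).
#' @param budgets,caps,n_zones as in [solve_constrained()].
#' @param lambda1_grid,lambda2_grid numeric grids of trade-off weights.
#' @return data.frame with one row per weight pair: `lambda1`, `lambda2`,
#'   `O`, `Y`, `C`, `E`.
#' @export
pareto_sweep <- function(params, budgets, caps, n_zones,
                         lambda1_grid = seq(0, 2, by = 0.5),
                         lambda2_grid = seq(0, 2, by = 0.5)) {
  rows <- list()
  for (l1 in lambda1_grid) for (l2 in lambda2_grid) {
    p <- objective_params(beta = params$beta, gamma = params$gamma,
                          costs = params$costs, env_costs = params$env_costs,
                          lambda1 = l1, lambda2 = l2)
    plan <- solve_constrained(p, budgets, caps, n_zones)
    vals <- objective_value(plan$U, p)
    rows[[length(rows) + 1L]] <- data.frame(
      lambda1 = l1, lambda2 = l2, O = vals$O, Y = vals$Y, C = vals$C,
      E = vals$E)
  }
  do.call(rbind, rows)
}
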