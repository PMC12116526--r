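# Ground-truth yield realization.

#' Realize per-zone yields under an allocation
#'
#' The generating yield model, shared with the optimizer's objective:
#' \deqn{Y_i = \beta_1 u_{i,w} + \beta_2 u_{i,f} + \beta_3 u_{i,p}
#'       - \gamma (u_{i,w} + u_{i,f} + u_{i,p})^2
#'       + w_{env}^\top (p_i - \bar p) + \eta_i,}
#' i.e. linear returns with a quadratic over-application penalty, plus a
#' linear environmental modifier (deviations of soil moisture, nutrient
#' index and canopy vigor from their long-run means, so stressed zones yield
#' less) and additive Gaussian disturbance \eqn{\eta_i \sim N(0,
#' \mathrm{noise\_sd}^2)} capturing pests, disease and unmodeled weather.
#' At the reference environment and `noise_sd = 0` this is exactly the
#' closed-form diminishing-returns response.
#'
#' @param scenario a [field_scenario] (supplies true beta, gamma, the
#'   environmental yield weights and `noise_sd`).
#' @param U `n_zones x 3` nonnegative allocation matrix
#'   (water, fertilizer, pesticide).
#' @param env an `env_state`; `NULL` evaluates at the reference environment
#'   (modifier 0).
#' @param seed integer seed for the disturbance draw.
#' @return numeric vector of `n_zones` yields.
#' @export
realize_yield <- function(scenario, U, env = NULL, seed = 1L) {
  stopifnot(inherits(scenario, "field_scenario"))
  U <- as_allocation_matrix(U, scenario$n_zones)
  if (any(U < 0))
    af_stop("allocations must be nonnegative",
            class = "agrifusion_validation_error")
  pars <- scenario$true_params
  base <- drop(U %*% pars$beta) - pars$gamma * rowSums(U)^2
  mod <- if (is.null(env)) 0 else yield_env_modifier(scenario, env)
  t_idx <- if (is.null(env)) 0L else env$t
  eta <- if (scenario$noise_sd > 0)
    with_seed(derive_seed(seed, 4L, t_idx),
              stats::rnorm(scenario$n_zones)) * scenario$noise_sd
  else rep(0, scenario$n_zones)
  base + mod + eta
}

# Linear environmental yield modifier: w_env . (p - mean), zero at the
# reference state.
yield_env_modifier <- function(scenario, env) {
  cfg <- scenario$env
  dev <- sweep(env$p[, cfg$names, drop = FALSE], 2L,
               cfg$means[cfg$names])
  drop(dev %*% cfg$yield_weights[cfg$names])
}

# Coerce an allocation to a numeric n x 3 matrix.
as_allocation_matrix <- function(U, n_zones) {
  if (inherits(U, "allocation_plan")) U <- U$U
  if (is.vector(U) && length(U) == 3L) U <- matrix(U, nrow = 1L)
  if (!is.matrix(U) || ncol(U) != 3L || nrow(U) != n_zones ||
      any(!is.finite(U)))
    af_stop(sprintf("allocation must be a finite %d x 3 matrix", n_zones),
            class = "agrifusion_validation_error")
  storage.mode(U) <- "double"
  colnames(U) <- c("water", "fertilizer", "pesticide")
  U
}
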