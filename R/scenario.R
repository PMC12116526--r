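# Synthetic multi-zone field scenarios with known ground truth.
#
# A scenario is the "world": the zone grid, the true yield-response
# parameters, resource budgets and per-zone caps, the environmental process
# and its noise levels, and the stress signatures. Everything downstream
# (detector, optimizer, controller) is exercised against it, so the true
# parameters are recorded explicitly.

#' Objective parameters of the yield / cost / environment trade-off
#'
#' Bundles the coefficients of the scalarized management objective
#' \deqn{O(U) = Y(U) - \lambda_1 C(U) - \lambda_2 E(U)}
#' where per zone \eqn{Y_i = \beta_1 u_w + \beta_2 u_f + \beta_3 u_p -
#' \gamma (u_w + u_f + u_p)^2} models diminishing returns, \eqn{C} is the
#' linear monetary cost and \eqn{E} the linear environmental cost of the
#' applied water, fertilizer and pesticide.
#'
#' @param beta length-3 yield coefficients per unit resource
#'   (water, fertilizer, pesticide).
#' @param gamma positive over-application penalty on the squared total input.
#' @param costs length-3 per-unit monetary costs.
#' @param env_costs length-3 per-unit environmental costs (e.g. runoff,
#'   emissions) in the same arbitrary impact units.
#' @param lambda1,lambda2 nonnegative trade-off weights on cost and
#'   environmental impact.
#' @return an object of class `objective_params`.
#' @export
objective_params <- function(beta = c(0.8, 0.6, 0.4),
                             gamma = 0.01,
                             costs = c(0.10, 0.20, 0.30),
                             env_costs = c(0.05, 0.10, 0.20),
                             lambda1 = 1,
                             lambda2 = 1) {
  if (!is.numeric(beta) || length(beta) != 3L || any(!is.finite(beta)))
    af_stop("field 'beta' must be a finite length-3 numeric vector",
            class = "agrifusion_validation_error")
  check_scalar(gamma, "gamma", function(v) v > 0, "positive")
  for (nm in c("costs", "env_costs")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 3L || any(!is.finite(v)) || any(v < 0))
      af_stop(sprintf("field '%s' must be three nonnegative numbers", nm),
              class = "agrifusion_validation_error")
  }
  check_scalar(lambda1, "lambda1", function(v) v >= 0, "nonnegative")
  check_scalar(lambda2, "lambda2", function(v) v >= 0, "nonnegative")
  structure(
    list(beta = as.double(beta), gamma = as.double(gamma),
         costs = as.double(costs), env_costs = as.double(env_costs),
         lambda1 = as.double(lambda1), lambda2 = as.double(lambda2)),
    class = "objective_params"
  )
}

#' @export
print.objective_params <- function(x, ...) {
  cat("Objective parameters\n")
  cat(sprintf("  beta  (yield/unit): %s\n", paste(x$beta, collapse = ", ")))
  cat(sprintf("  gamma (over-application penalty): %g\n", x$gamma))
  cat(sprintf("  costs: %s   env costs: %s\n",
              paste(x$costs, collapse = ", "),
              paste(x$env_costs, collapse = ", ")))
  cat(sprintf("  lambda1 = %g, lambda2 = %g\n", x$lambda1, x$lambda2))
  invisible(x)
}

# Environmental state variables tracked per zone. Soil moisture, nutrient
# index and canopy vigor live on [0,1]; temperature in degrees C. "Vigor" is
# an NDVI-like canopy condition index that every stress archetype depresses.
env_variable_defaults <- function() {
  list(
    names = c("moisture", "temperature", "nutrient", "vigor"),
    means = c(moisture = 0.6, temperature = 22, nutrient = 0.7, vigor = 0.85),
    innovation_sd = c(moisture = 0.05, temperature = 1.0,
                      nutrient = 0.03, vigor = 0.03),
    lower = c(moisture = 0, temperature = -Inf, nutrient = 0, vigor = 0),
    upper = c(moisture = 1, temperature = Inf, nutrient = 1, vigor = 1),
    ar = 0.8,
    # linear yield modifier: yield_i += sum_v w_v * (p_iv - mean_v);
    # positive weights so that depressed moisture/nutrient/vigor reduce yield
    yield_weights = c(moisture = 2, temperature = 0, nutrient = 2, vigor = 3)
  )
}

# Per-variable mean shifts applied by each stress archetype, scaled by
# severity. Magnitudes are package constants chosen to give clearly
# separated feature distributions at severity 1 while staying inside the
# variables' physical ranges.
stress_signature_defaults <- function() {
  list(
    drought = c(moisture = -0.4, temperature = 1.5, nutrient = 0,
                vigor = -0.3),
    nutrient_deficiency = c(moisture = 0, temperature = 0, nutrient = -0.5,
                            vigor = -0.2),
    fungal_infection = c(moisture = 0.05, temperature = 0, nutrient = 0,
                         vigor = -0.4),
    insect_pest = c(moisture = 0, temperature = 0, nutrient = 0,
                    vigor = -0.35),
    # additional imagery texture noise (sd per unit severity) rendered inside
    # affected zones: lesion speckle for fungal infection, chewing-damage
    # texture for insect pests
    texture_sd = c(drought = 0, nutrient_deficiency = 0,
                   fungal_infection = 0.15, insect_pest = 0.10)
  )
}

#' Create a synthetic field scenario
#'
#' Defines a field of `n_zones` management zones laid out row-major on a
#' `grid_shape` grid (zone `k`, 0-based, occupies cell
#' `(k %/% cols, k %% cols)`), together with the true yield-response
#' parameters, resource budgets, per-zone caps, environmental dynamics and
#' observation model. All downstream sampling is deterministic given `seed`.
#'
#' @param n_zones number of zones (N >= 1).
#' @param grid_shape integer `(rows, cols)` with `rows * cols == n_zones`.
#'   Defaults to a single row.
#' @param true_params [objective_params] holding the generating coefficients.
#' @param budgets length-3 nonnegative totals `(B_water, B_fert, B_pest)`.
#' @param caps per-zone allocation caps: length-3 vector recycled to all
#'   zones, or an `n_zones x 3` matrix.
#' @param noise_sd standard deviation of the additive yield disturbance
#'   \eqn{\eta}.
#' @param env_corr_length spatial correlation length (grid cells) of the
#'   Gaussian-kernel correlated environmental innovations.
#' @param env optional overrides for the environmental process (see
#'   `env_variable_defaults()`).
#' @param obs observation-model settings: satellite grid `sat_dim`
#'   (H, W, channels), UAV grid `uav_dim`, sensor noise `sensor_sd`, imagery
#'   render noise `render_sd`, weather window `t_w` and dimension `d_w`.
#' @param seed integer master seed for the scenario's random streams.
#' @return an object of class `field_scenario`.
#' @examples
#' sc <- field_scenario(n_zones = 4, seed = 7)
#' sc$grid_shape
#' @export
field_scenario <- function(n_zones = 16,
                           grid_shape = NULL,
                           true_params = objective_params(),
                           budgets = c(20, 10, 5) * n_zones,
                           caps = c(30, 20, 10),
                           noise_sd = 0.5,
                           env_corr_length = 1.5,
                           env = list(),
                           obs = list(),
                           seed = 1L) {
  check_scalar(n_zones, "n_zones", function(v) v >= 1 && v == round(v),
               "positive integer")
  n_zones <- as.integer(n_zones)
  if (is.null(grid_shape)) grid_shape <- c(1L, n_zones)
  if (length(grid_shape) != 2L || any(grid_shape < 1) ||
      prod(grid_shape) != n_zones)
    af_stop("field 'grid_shape' must be (rows, cols) with rows*cols == n_zones",
            class = "agrifusion_validation_error")
  if (!inherits(true_params, "objective_params"))
    af_stop("field 'true_params' must be an objective_params object",
            class = "agrifusion_validation_error")
  if (!is.numeric(budgets) || length(budgets) != 3L || any(budgets < 0) ||
      any(!is.finite(budgets) & budgets != Inf))
    af_stop("field 'budgets' must be three nonnegative numbers",
            class = "agrifusion_validation_error")
  caps <- expand_caps(caps, n_zones)
  check_scalar(noise_sd, "noise_sd", function(v) v >= 0, "nonnegative")
  check_scalar(env_corr_length, "env_corr_length", function(v) v >= 0,
               "nonnegative")
  check_scalar(seed, "seed", function(v) v == round(v), "integer")

  env_cfg <- utils::modifyList(env_variable_defaults(), env)
  obs_cfg <- utils::modifyList(
    list(sat_dim = c(8L, 8L, 3L), uav_dim = c(16L, 16L, 3L),
         sensor_sd = 0.02, render_sd = 0.05,
         t_w = 24L, d_w = 4L,
         weather_means = c(temp = 20, humidity = 0.6, wind = 3, precip = 1),
         weather_sd = c(1.5, 0.05, 0.5, 0.5), weather_ar = 0.7),
    obs)

  structure(
    list(n_zones = n_zones,
         grid_shape = as.integer(grid_shape),
         true_params = true_params,
         budgets = stats::setNames(as.double(budgets),
                                   c("water", "fertilizer", "pesticide")),
         caps = caps,
         noise_sd = as.double(noise_sd),
         env_corr_length = as.double(env_corr_length),
         env = env_cfg,
         obs = obs_cfg,
         stress = stress_signature_defaults(),
         seed = as.integer(seed)),
    class = "field_scenario"
  )
}

expand_caps <- function(caps, n_zones) {
  if (is.matrix(caps)) {
    if (nrow(caps) != n_zones || ncol(caps) != 3L)
      af_stop("field 'caps' matrix must be n_zones x 3",
              class = "agrifusion_validation_error")
  } else if (length(caps) == 3L) {
    caps <- matrix(rep(as.double(caps), each = n_zones), nrow = n_zones)
  } else {
    af_stop("field 'caps' must be length 3 or an n_zones x 3 matrix",
            class = "agrifusion_validation_error")
  }
  if (any(caps < 0))
    af_stop("field 'caps' must be nonnegative",
            class = "agrifusion_validation_error")
  colnames(caps) <- c("water", "fertilizer", "pesticide")
  caps
}

#' Map zones to grid cells (row-major, 0-based)
#'
#' @param scenario a [field_scenario].
#' @return data.frame with `zone_id`, `row`, `col` (all 0-based).
#' @export
zone_grid <- function(scenario) {
  stopifnot(inherits(scenario, "field_scenario"))
  k <- seq_len(scenario$n_zones) - 1L
  cols <- scenario$grid_shape[2L]
  data.frame(zone_id = k, row = k %/% cols, col = k %% cols)
}

# Pairwise Euclidean distances between zone grid cells.
zone_distances <- function(scenario) {
  g <- zone_grid(scenario)
  as.matrix(stats::dist(cbind(g$row, g$col)))
}

#' @export
print.field_scenario <- function(x, ...) {
  cat(sprintf("Field scenario: %d zones on a %d x %d grid (seed %d)\n",
              x$n_zones, x$grid_shape[1L], x$grid_shape[2L], x$seed))
  cat(sprintf("  budgets (w/f/p): %s\n", paste(x$budgets, collapse = " / ")))
  cat(sprintf("  yield noise sd: %g, env correlation length: %g cells\n",
              x$noise_sd, x$env_corr_length))
  invisible(x)
}

#' Declare a stress event
#'
#' A stress event shifts the environmental state of the listed zones by a
#' per-variable signature scaled by `severity`, between `onset` and
#' `onset + duration - 1` (half-open time convention elsewhere; events are
#' active while `onset <= t < onset + duration`).
#'
#' @param zone_ids nonempty 0-based zone indices.
#' @param stress_type one of `"drought"`, `"nutrient_deficiency"`,
#'   `"fungal_infection"`, `"insect_pest"`.
#' @param severity severity in [0, 1].
#' @param onset first active time step (default 0).
#' @param duration number of active steps (default `Inf`, i.e. permanent).
#' @return an object of class `stress_event`.
#' @export
stress_event <- function(zone_ids, stress_type, severity,
                         onset = 0L, duration = Inf) {
  types <- c("drought", "nutrient_deficiency", "fungal_infection",
             "insect_pest")
  if (!is.character(stress_type) || length(stress_type) != 1L ||
      !(stress_type %in% types))
    af_stop(sprintf("unknown stress_type '%s' (expected one of: %s)",
                    as.character(stress_type)[1L],
                    paste(types, collapse = ", ")),
            class = "agrifusion_validation_error")
  if (length(zone_ids) < 1L || any(zone_ids < 0) ||
      any(zone_ids != round(zone_ids)))
    af_stop("field 'zone_ids' must be a nonempty set of 0-based zone indices",
            class = "agrifusion_validation_error")
  check_scalar(severity, "severity", function(v) v >= 0 && v <= 1,
               "in [0, 1]")
  structure(
    list(zone_ids = as.integer(zone_ids), stress_type = stress_type,
         severity = as.double(severity), onset = as.double(onset),
         duration = as.double(duration)),
    class = "stress_event"
  )
}

# Events active at time t (onset <= t < onset + duration).
active_events <- function(events, t) {
  Filter(function(e) t >= e$onset && t < e$onset + e$duration, events)
}
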