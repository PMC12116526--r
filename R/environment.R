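# Environmental dynamics: spatially correlated AR(1) per-zone states plus a
# field-level weather series.

#' Sample the environmental state of the field at one time step
#'
#' Each per-zone variable follows an AR(1) process around its long-run mean,
#' with innovations that are spatially correlated across zones through a
#' Gaussian kernel on grid distance:
#' \deqn{p_v(t) = \mu_v + \phi (p_v(t-1) - \mu_v) + \epsilon_v(t), \quad
#'       \epsilon_v(t) \sim N(0, \sigma_v^2 K),}
#' \eqn{K_{ij} = \exp(-d_{ij}^2 / (2\ell^2))} with \eqn{\ell} the scenario's
#' `env_corr_length` (as \eqn{\ell \to 0}, innovations become independent
#' across zones). At `t = 0` (no previous state) the process starts from its
#' stationary distribution. Bounded variables (soil moisture, nutrient
#' index, canopy vigor) are clipped to [0, 1] after the update. The weather
#' series is a field-level AR(1) window of the most recent `t_w` steps.
#'
#' Sampling is deterministic given the scenario seed and `t`
#' (sub-stream offsets 1 and 2 of [derive_seed()]).
#'
#' @param scenario a [field_scenario].
#' @param t time index, `t >= 0`.
#' @param prev the `env_state` at `t - 1`, or `NULL` for a fresh start.
#' @return an object of class `env_state` with fields `t`, `p`
#'   (`n_zones x 4` matrix: moisture, temperature, nutrient, vigor) and
#'   `weather` (`t_w x d_w` matrix).
#' @export
sample_environment <- function(scenario, t, prev = NULL) {
  stopifnot(inherits(scenario, "field_scenario"))
  check_scalar(t, "t", function(v) v >= 0 && v == round(v),
               "nonnegative integer")
  if (!is.null(prev) && !inherits(prev, "env_state"))
    af_stop("'prev' must be an env_state or NULL",
            class = "agrifusion_validation_error")

  cfg <- scenario$env
  n <- scenario$n_zones
  vars <- cfg$names
  L <- spatial_chol(scenario)

  p <- with_seed(derive_seed(scenario$seed, 1L, t), {
    out <- matrix(NA_real_, n, length(vars), dimnames = list(NULL, vars))
    for (v in vars) {
      sdv <- cfg$innovation_sd[[v]]
      innov <- if (sdv > 0) drop(crossprod(L, stats::rnorm(n))) * sdv
               else {
                 stats::rnorm(n) # burn the draw so streams stay aligned
                 rep(0, n)
               }
      mu <- cfg$means[[v]]
      if (is.null(prev)) {
        scale <- if (cfg$ar < 1) 1 / sqrt(1 - cfg$ar^2) else 1
        out[, v] <- mu + innov * scale
      } else {
        out[, v] <- mu + cfg$ar * (prev$p[, v] - mu) + innov
      }
    }
    out
  })
  for (v in vars) p[, v] <- clip(p[, v], cfg$lower[[v]], cfg$upper[[v]])

  weather <- sample_weather(scenario, t, prev)

  structure(list(t = as.integer(t), p = p, weather = weather),
            class = "env_state")
}

# Cholesky factor of the Gaussian-kernel spatial correlation matrix, with a
# small jitter for numerical definiteness. env_corr_length == 0 degenerates
# to independent zones.
spatial_chol <- function(scenario) {
  n <- scenario$n_zones
  ell <- scenario$env_corr_length
  if (n == 1L) return(matrix(1, 1, 1))
  if (ell <= 0) return(diag(n))
  d <- zone_distances(scenario)
  K <- exp(-d^2 / (2 * ell^2))
  chol(K + diag(1e-10, n))
}

sample_weather <- function(scenario, t, prev) {
  o <- scenario$obs
  mu <- as.double(o$weather_means)
  sdw <- as.double(o$weather_sd)
  ar <- o$weather_ar
  d_w <- as.integer(o$d_w)
  t_w <- as.integer(o$t_w)
  with_seed(derive_seed(scenario$seed, 2L, t), {
    step <- function(last) mu + ar * (last - mu) + stats::rnorm(d_w) * sdw
    if (is.null(prev)) {
      w <- matrix(NA_real_, t_w, d_w,
                  dimnames = list(NULL, names(o$weather_means)))
      scale <- if (ar < 1) 1 / sqrt(1 - ar^2) else 1
      last <- mu + stats::rnorm(d_w) * sdw * scale
      w[1L, ] <- last
      for (i in seq_len(t_w - 1L)) {
        last <- step(last)
        w[i + 1L, ] <- last
      }
      w
    } else {
      rbind(prev$weather[-1L, , drop = FALSE],
            step(prev$weather[nrow(prev$weather), ]))
    }
  })
}

#' @export
print.env_state <- function(x, ...) {
  cat(sprintf("Environmental state at t = %d (%d zones)\n", x$t, nrow(x$p)))
  print(round(utils::head(x$p, 4L), 3))
  if (nrow(x$p) > 4L) cat(sprintf("  ... %d more zones\n", nrow(x$p) - 4L))
  invisible(x)
}

#' Apply stress events to an environmental state
#'
#' Each event shifts its target zones' variables by the stress signature
#' scaled by severity (see `stress_signature_defaults()`); e.g. drought at
#' severity 1 lowers soil moisture by 0.4 and canopy vigor by 0.3. Shifts of
#' all events are accumulated additively and bounded variables are clipped
#' once at the end, so events with disjoint zone sets commute. Zones not
#' targeted by any event are untouched.
#'
#' @param env an `env_state`.
#' @param events list of [stress_event] objects (a single event is accepted).
#' @param scenario the owning [field_scenario] (supplies the signatures).
#' @return the shifted `env_state`.
#' @export
inject_stress <- function(env, events, scenario) {
  stopifnot(inherits(env, "env_state"), inherits(scenario, "field_scenario"))
  if (inherits(events, "stress_event")) events <- list(events)
  p <- env$p
  for (e in events) {
    if (!inherits(e, "stress_event"))
      af_stop("events must be stress_event objects",
              class = "agrifusion_validation_error")
    if (any(e$zone_ids >= scenario$n_zones))
      af_stop(sprintf("stress event targets zone %d outside [0, %d)",
                      max(e$zone_ids), scenario$n_zones),
              class = "agrifusion_validation_error")
    sig <- scenario$stress[[e$stress_type]]
    if (is.null(sig))
      af_stop(sprintf("unknown stress_type '%s'", e$stress_type),
              class = "agrifusion_validation_error")
    idx <- e$zone_ids + 1L
    for (v in names(sig)) {
      p[idx, v] <- p[idx, v] + sig[[v]] * e$severity
    }
  }
  cfg <- scenario$env
  for (v in cfg$names) p[, v] <- clip(p[, v], cfg$lower[[v]], cfg$upper[[v]])
  env$p <- p
  env
}
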