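# Configuration: nested defaults, strict schema validation, YAML/JSON
# round-trip, and construction of scenario objects from configs.

#' Default configuration
#'
#' The full nested configuration with every tunable of the pipeline:
#' scenario geometry and noise, generating objective parameters, detector
#' settings, fusion dimensions, solver controls, controller gains, and the
#' master seed. `budgets: null` means "derive from the zone count"
#' (20/10/5 units of water/fertilizer/pesticide per zone).
#'
#' @return nested named list.
#' @export
default_config <- function() {
  list(
    scenario = list(n_zones = 16L, grid_shape = c(4L, 4L),
                    budgets = NULL, caps = c(30, 20, 10),
                    noise_sd = 0.5, env_corr_length = 1.5),
    params = list(beta = c(0.8, 0.6, 0.4), gamma = 0.01,
                  costs = c(0.10, 0.20, 0.30),
                  env_costs = c(0.05, 0.10, 0.20),
                  lambda1 = 1, lambda2 = 1),
    detector = list(shrinkage = 0.1, metric = "mahalanobis", q = 0.95),
    fusion = list(d = 16L, d_k = 8L),
    solver = list(tol = 1e-10, max_iter = 10000L),
    controller = list(alpha = 0.05, alpha_r = c(0.10, 0.05, 0.01),
                      beta_vec = c(-0.5, 0, -0.5, -0.5), steps = 20L),
    seed = 1L
  )
}

# Recursively check cfg against the default schema; collect unknown keys.
unknown_keys <- function(cfg, ref, prefix = "") {
  bad <- character(0)
  if (!is.list(cfg)) return(bad)
  for (nm in names(cfg)) {
    if (!(nm %in% names(ref))) {
      bad <- c(bad, paste0(prefix, nm))
    } else if (is.list(ref[[nm]]) && !is.null(names(ref[[nm]]))) {
      bad <- c(bad, unknown_keys(cfg[[nm]], ref[[nm]],
                                 paste0(prefix, nm, ".")))
    }
  }
  bad
}

merge_config <- function(defaults, cfg) {
  for (nm in names(cfg)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]])) &&
        is.list(cfg[[nm]])) {
      defaults[[nm]] <- merge_config(defaults[[nm]], cfg[[nm]])
    } else {
      defaults[[nm]] <- cfg[[nm]]
    }
  }
  defaults
}

#' Load and validate a configuration file
#'
#' Reads YAML (`.yaml`/`.yml`) or JSON (`.json`), rejects unknown keys
#' (listing every offender, a typo guard), fills missing keys with the
#' defaults of [default_config()], and validates value constraints.
#'
#' @param path file path.
#' @return validated configuration list (class `scenario_config`) with all
#'   defaults filled.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    af_stop(sprintf("config file not found: %s", path),
            class = "agrifusion_io_error")
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path,
                                                     simplifyVector = TRUE)
         else af_stop(sprintf("unsupported config format '.%s'", ext),
                      class = "agrifusion_io_error")
  validate_config(raw)
}

#' Validate a configuration list
#'
#' @param raw possibly partial configuration list.
#' @return completed, validated `scenario_config`.
#' @export
validate_config <- function(raw) {
  if (is.null(raw)) raw <- list()
  defaults <- default_config()
  bad <- unknown_keys(raw, defaults)
  if (length(bad))
    af_stop(paste0("unknown config key(s): ", paste(bad, collapse = ", ")),
            class = "agrifusion_validation_error")
  cfg <- merge_config(defaults, raw)
  check_scalar(cfg$scenario$n_zones, "scenario.n_zones",
               function(v) v >= 1 && v == round(v), "positive integer")
  if (is.null(cfg$scenario$grid_shape) ||
      prod(cfg$scenario$grid_shape) != cfg$scenario$n_zones)
    cfg$scenario$grid_shape <- c(1L, as.integer(cfg$scenario$n_zones))
  check_scalar(cfg$params$gamma, "params.gamma", function(v) v > 0,
               "positive")
  check_scalar(cfg$detector$q, "detector.q", function(v) v > 0 && v < 1,
               "in (0, 1)")
  check_scalar(cfg$seed, "seed", function(v) v == round(v), "integer")
  if (is.null(cfg$scenario$budgets))
    cfg$scenario$budgets <- c(20, 10, 5) * cfg$scenario$n_zones
  structure(cfg, class = c("scenario_config", "list"))
}

#' Write a configuration to YAML or JSON
#'
#' @param cfg configuration list.
#' @param path destination (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- unclass(cfg)
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(cfg, path)
  } else if (ext == "json") {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else {
    af_stop(sprintf("unsupported config format '.%s'", ext),
            class = "agrifusion_io_error")
  }
  invisible(path)
}

#' Fingerprint of a configuration
#'
#' FNV-1a hash of the canonical JSON serialization; logged in every run
#' manifest so outputs can be traced to the exact configuration.
#'
#' @param cfg configuration list.
#' @return 8-hex-digit string.
#' @export
config_hash <- function(cfg) {
  fnv1a_hash(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              null = "null"))
}

#' Build a field scenario from a configuration
#'
#' @param cfg a validated `scenario_config` (see [load_config()]).
#' @return a [field_scenario].
#' @export
scenario_from_config <- function(cfg) {
  cfg <- validate_config(unclass(cfg))
  s <- cfg$scenario
  field_scenario(
    n_zones = s$n_zones,
    grid_shape = s$grid_shape,
    true_params = objective_params(beta = cfg$params$beta,
                                   gamma = cfg$params$gamma,
                                   costs = cfg$params$costs,
                                   env_costs = cfg$params$env_costs,
                                   lambda1 = cfg$params$lambda1,
                                   lambda2 = cfg$params$lambda2),
    budgets = s$budgets,
    caps = s$caps,
    noise_sd = s$noise_sd,
    env_corr_length = s$env_corr_length,
    seed = cfg$seed
  )
}
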