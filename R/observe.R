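# Rendering of multimodal observations from the latent field state.

#' Construct a multimodal observation
#'
#' Container for one time step's four-modality snapshot: a satellite feature
#' grid `H_s x W_s x d_s`, a strictly finer UAV grid `H_u x W_u x d_u`, a
#' ground-sensor matrix `N_g x d_g` and a weather series `T_w x d_w`.
#'
#' @param x_sat,x_uav 3-d arrays (height, width, channels).
#' @param x_sens,x_weather matrices.
#' @return an object of class `multimodal_observation`.
#' @export
multimodal_observation <- function(x_sat, x_uav, x_sens, x_weather) {
  for (nm in c("x_sat", "x_uav")) {
    a <- get(nm)
    if (!is.array(a) || length(dim(a)) != 3L || any(!is.finite(a)))
      af_stop(sprintf("field '%s' must be a finite 3-d array", nm),
              class = "agrifusion_validation_error")
  }
  for (nm in c("x_sens", "x_weather")) {
    m <- get(nm)
    if (!is.matrix(m) || any(!is.finite(m)))
      af_stop(sprintf("field '%s' must be a finite matrix", nm),
              class = "agrifusion_validation_error")
  }
  structure(list(x_sat = x_sat, x_uav = x_uav, x_sens = x_sens,
                 x_weather = x_weather),
            class = "multimodal_observation")
}

#' @export
print.multimodal_observation <- function(x, ...) {
  cat("Multimodal observation\n")
  cat(sprintf("  satellite: %s   uav: %s\n",
              paste(dim(x$x_sat), collapse = "x"),
              paste(dim(x$x_uav), collapse = "x")))
  cat(sprintf("  sensors:   %s   weather: %s\n",
              paste(dim(x$x_sens), collapse = "x"),
              paste(dim(x$x_weather), collapse = "x")))
  invisible(x)
}

#' Render multimodal observations of a field state
#'
#' Produces the four-modality snapshot implied by an environmental state:
#' satellite and UAV imagery are smooth per-zone fields (channels: canopy
#' vigor, soil moisture, nutrient index) upsampled from the zone grid with
#' additive Gaussian render noise; ground sensors report each zone's
#' environmental vector plus sensor noise; the weather block is copied from
#' the state. Fungal-infection events additionally overlay lesion-like
#' speckle and insect-pest events a chewing-damage texture (zero-mean noise
#' with sd proportional to severity) inside affected zones' pixels, so
#' stressed zones are displaced in both mean (through the state shift) and
#' texture.
#'
#' @param scenario a [field_scenario].
#' @param env an `env_state` (already stress-shifted if applicable).
#' @param events stress events used for imagery texture signatures
#'   (default none).
#' @param seed integer seed; rendering is deterministic given
#'   `(seed, env$t)`.
#' @return a [multimodal_observation].
#' @export
render_observations <- function(scenario, env, events = list(), seed = 1L) {
  stopifnot(inherits(scenario, "field_scenario"), inherits(env, "env_state"))
  if (inherits(events, "stress_event")) events <- list(events)
  o <- scenario$obs
  channels <- c("vigor", "moisture", "nutrient")
  zone_vals <- env$p[, channels, drop = FALSE]

  with_seed(derive_seed(seed, 3L, env$t), {
    x_sat <- render_grid(scenario, zone_vals, o$sat_dim, o$render_sd, events)
    x_uav <- render_grid(scenario, zone_vals, o$uav_dim, o$render_sd, events)
    noise <- matrix(stats::rnorm(length(env$p)), nrow(env$p)) * o$sensor_sd
    x_sens <- env$p + noise
    multimodal_observation(x_sat, x_uav, x_sens, env$weather)
  })
}

# Upsample per-zone channel values to an H x W x C array (nearest zone cell)
# and add render noise plus stress texture.
render_grid <- function(scenario, zone_vals, dims, render_sd, events) {
  h <- dims[1L]; w <- dims[2L]; nc <- dims[3L]
  rows <- scenario$grid_shape[1L]; cols <- scenario$grid_shape[2L]
  # pixel (a, b), 1-based -> zone cell, row-major 0-based
  zr <- pmin(rows - 1L, floor((seq_len(h) - 1L) / h * rows))
  zc <- pmin(cols - 1L, floor((seq_len(w) - 1L) / w * cols))
  zone_of_pixel <- outer(zr, zc, function(r, c) r * cols + c) + 1L
  arr <- array(0, dim = c(h, w, nc))
  for (ch in seq_len(nc)) {
    vals <- if (ch <= ncol(zone_vals)) zone_vals[, ch] else
      rep(0, nrow(zone_vals))
    arr[, , ch] <- matrix(vals[zone_of_pixel], h, w)
  }
  if (render_sd > 0) arr <- arr + array(stats::rnorm(h * w * nc), dim(arr)) *
      render_sd
  tex <- scenario$stress$texture_sd
  for (e in events) {
    sdt <- tex[[e$stress_type]]
    if (is.null(sdt) || sdt == 0 || e$severity == 0) next
    mask <- matrix(zone_of_pixel %in% (e$zone_ids + 1L), h, w)
    n_px <- sum(mask)
    for (ch in seq_len(nc)) {
      layer <- arr[, , ch]
      layer[mask] <- layer[mask] + stats::rnorm(n_px) * sdt * e$severity
      arr[, , ch] <- layer
    }
  }
  arr
}

#' Summarize an observation into per-zone feature vectors
#'
#' Aggregates each modality to the zone level: per-zone channel means of the
#' satellite and UAV grids plus the ground-sensor vector, giving one
#' d-dimensional feature row per zone (d = d_s + d_u + d_g with the default
#' configuration). The weather block is field-level and is left to the
#' temporal fusion path rather than duplicated into every zone.
#'
#' @param obs a [multimodal_observation].
#' @param scenario the owning [field_scenario].
#' @return an `n_zones x d` numeric matrix with named columns.
#' @export
zone_features <- function(obs, scenario) {
  stopifnot(inherits(obs, "multimodal_observation"),
            inherits(scenario, "field_scenario"))
  sat <- per_zone_channel_means(obs$x_sat, scenario)
  uav <- per_zone_channel_means(obs$x_uav, scenario)
  colnames(sat) <- paste0("sat_", seq_len(ncol(sat)))
  colnames(uav) <- paste0("uav_", seq_len(ncol(uav)))
  sens <- obs$x_sens
  colnames(sens) <- paste0("sens_", seq_len(ncol(sens)))
  cbind(sat, uav, sens)
}

per_zone_channel_means <- function(arr, scenario) {
  h <- dim(arr)[1L]; w <- dim(arr)[2L]; nc <- dim(arr)[3L]
  rows <- scenario$grid_shape[1L]; cols <- scenario$grid_shape[2L]
  zr <- pmin(rows - 1L, floor((seq_len(h) - 1L) / h * rows))
  zc <- pmin(cols - 1L, floor((seq_len(w) - 1L) / w * cols))
  zone_of_pixel <- outer(zr, zc, function(r, c) r * cols + c) + 1L
  zone_f <- factor(as.vector(zone_of_pixel),
                   levels = seq_len(scenario$n_zones))
  out <- matrix(NA_real_, scenario$n_zones, nc)
  for (ch in seq_len(nc)) {
    layer <- arr[, , ch]
    out[, ch] <- as.vector(tapply(as.vector(layer), zone_f, mean))
  }
  out
}
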