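# Multimodal fusion mathematics: per-modality encoding and shared-space
# projection, softmax modality weighting, spatial attention, temporal
# aggregation, and cross-modal scaled dot-product attention with residual
# fusion and self-attention refinement. Everything is small-tensor, CPU-only
# linear algebra; weights are plain matrices so contracts can be verified
# against closed forms and brute-force oracles.

#' Initialize fusion parameters
#'
#' Creates the full parameter set: per-modality encoders `E_m` and
#' projections `P_m` into the shared latent space of dimension `d`,
#' per-modality score weights `W_m` for softmax modality weighting, shared
#' attention projections `W_q`, `W_k` (to key dimension `d_k`) and `W_v`
#' (to `d`), a learned global query token for modality-sum fusion, a 1x1
#' convolution weight for spatial attention, and recurrent/temporal
#' weights. Entries are drawn N(0, 1/d), deterministic given `seed`.
#'
#' @param modality_dims named list giving each modality's token feature
#'   dimension, e.g. `list(sat = 3, uav = 3, ground = 4, weather = 4)`.
#' @param d shared latent dimension (default 16).
#' @param d_k key dimension of the attention projections (default 8).
#' @param seed integer seed.
#' @return an object of class `encoder_params`.
#' @export
encoder_params <- function(modality_dims = list(sat = 3, uav = 3,
                                                ground = 4, weather = 4),
                           d = 16, d_k = 8, seed = 1L) {
  check_scalar(d, "d", function(v) v >= 1 && v == round(v),
               "positive integer")
  check_scalar(d_k, "d_k", function(v) v >= 1 && v == round(v),
               "positive integer")
  if (length(modality_dims) < 1L || is.null(names(modality_dims)))
    af_stop("modality_dims must be a named list of input dimensions",
            class = "agrifusion_validation_error")
  with_seed(derive_seed(seed, 5L, 0L), {
    rmat <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(d)),
                                    nr, nc)
    enc <- lapply(modality_dims, function(d_in) rmat(d_in, d))
    proj <- lapply(modality_dims, function(d_in) rmat(d, d))
    score_w <- lapply(modality_dims, function(d_in) stats::rnorm(d, sd = 1))
    structure(
      list(d = as.integer(d), d_k = as.integer(d_k),
           modality_dims = modality_dims,
           encoders = enc, projections = proj, score_weights = score_w,
           w_q = rmat(d, d_k), w_k = rmat(d, d_k), w_v = rmat(d, d),
           global_query = rmat(1L, d),
           spatial_w = stats::rnorm(d, sd = 1 / sqrt(d)), spatial_b = 0,
           recurrent = list(w_h = rmat(d, d), u_h = rmat(d, d),
                            b_h = rep(0, d)),
           seed = as.integer(seed)),
      class = "encoder_params"
    )
  })
}

#' @export
print.encoder_params <- function(x, ...) {
  cat(sprintf("Fusion parameters: d = %d, d_k = %d, modalities: %s\n",
              x$d, x$d_k, paste(names(x$modality_dims), collapse = ", ")))
  invisible(x)
}

# Flatten a modality input to a token matrix (n_tokens x d_in), keeping the
# spatial layout as an attribute for spatial modalities.
as_tokens <- function(x, name) {
  if (is.array(x) && length(dim(x)) == 3L) {
    dm <- dim(x)
    tok <- matrix(x, nrow = dm[1L] * dm[2L], ncol = dm[3L])
    attr(tok, "layout") <- dm[1:2]
    tok
  } else if (is.matrix(x)) {
    x
  } else {
    af_stop(sprintf("modality '%s' must be a matrix or 3-d array", name),
            class = "agrifusion_validation_error")
  }
}

#' Encode each modality and project into the shared latent space
#'
#' Applies the modality-specific linear encoder `F_m = X_m E_m` followed by
#' the projection `F_proj_m = F_m P_m`, mapping every modality to tokens of
#' the shared dimension `d`. Spatial modalities (3-d arrays) keep their
#' `(H, W)` token layout as an attribute; the sensor matrix yields one
#' token per sensor and the weather series one token per time step. Linear
#' maps, no bias.
#'
#' @param obs a [multimodal_observation], or a named list of raw modality
#'   inputs matching `params$modality_dims`.
#' @param params an [encoder_params].
#' @return named list of `n_m x d` token matrices.
#' @export
encode_and_project <- function(obs, params) {
  stopifnot(inherits(params, "encoder_params"))
  inputs <- if (inherits(obs, "multimodal_observation")) {
    list(sat = obs$x_sat, uav = obs$x_uav, ground = obs$x_sens,
         weather = obs$x_weather)[names(params$modality_dims)]
  } else obs
  out <- list()
  for (m in names(params$modality_dims)) {
    if (is.null(inputs[[m]]))
      af_stop(sprintf("missing input for modality '%s'", m),
              class = "agrifusion_validation_error")
    tok <- as_tokens(inputs[[m]], m)
    d_in <- nrow(params$encoders[[m]])
    if (ncol(tok) != d_in)
      af_stop(sprintf(
        "modality '%s': token dimension %d does not match encoder input %d",
        m, ncol(tok), d_in), class = "agrifusion_validation_error")
    f <- tok %*% params$encoders[[m]] %*% params$projections[[m]]
    attr(f, "layout") <- attr(tok, "layout")
    out[[m]] <- f
  }
  out
}

#' Softmax modality weights
#'
#' Each modality receives a scalar relevance score, the mean of the entries
#' of `F_m W_m`; the weights are the softmax of the scores across
#' modalities, so they are positive, sum to 1, and are invariant to adding
#' a constant to every score.
#'
#' @param f_list named list of token matrices (`n_m x d`).
#' @param w_list matching list of score weights (d-vector or `d x k`
#'   matrix per modality).
#' @return named weight vector summing to 1.
#' @export
modality_weights <- function(f_list, w_list) {
  if (length(f_list) == 0L)
    af_stop("modality list is empty", class = "agrifusion_validation_error")
  if (length(w_list) != length(f_list))
    af_stop("need one score weight per modality",
            class = "agrifusion_validation_error")
  scores <- vapply(seq_along(f_list), function(i) {
    mean(as.matrix(f_list[[i]]) %*% as.matrix(w_list[[i]]))
  }, numeric(1))
  stats::setNames(softmax(scores), names(f_list))
}

#' Spatial attention over a feature map
#'
#' Scores each location with a 1x1 convolution (a channel-weighted sum plus
#' bias), applies a softmax over all `H x W` locations to get the attention
#' map `A`, and reweights the feature map by the Hadamard product broadcast
#' over channels. `sum(A) == 1`.
#'
#' @param f_map `H x W x d` array.
#' @param w channel weight d-vector (default: the params' spatial weight).
#' @param b scalar bias (default 0).
#' @return list with `A` (`H x W`, sums to 1) and `f_att` (`H x W x d`).
#' @export
spatial_attention <- function(f_map, w, b = 0) {
  if (!is.array(f_map) || length(dim(f_map)) != 3L)
    af_stop("spatial attention needs an H x W x d array",
            class = "agrifusion_validation_error")
  dm <- dim(f_map)
  if (length(w) != dm[3L])
    af_stop("spatial score weight length must equal the channel dimension",
            class = "agrifusion_validation_error")
  flat <- matrix(f_map, nrow = dm[1L] * dm[2L], ncol = dm[3L])
  logits <- drop(flat %*% w) + b
  a <- matrix(softmax(logits), dm[1L], dm[2L])
  f_att <- f_map * array(rep(a, dm[3L]), dm)
  list(A = a, f_att = f_att)
}

#' Scaled dot-product attention
#'
#' `C = softmax(Q K^T / sqrt(d_k))` row-wise, `out = C V`. Every row of `C`
#' is a convex weight vector over the keys.
#'
#' @param q,k,v query (`n_q x d_k`), key (`n_k x d_k`) and value
#'   (`n_k x d_v`) matrices.
#' @param d_k key dimension used in the scaling (default `ncol(k)`).
#' @return list with `C` (`n_q x n_k`) and `out` (`n_q x d_v`).
#' @export
scaled_dot_attention <- function(q, k, v, d_k = ncol(k)) {
  q <- as.matrix(q); k <- as.matrix(k); v <- as.matrix(v)
  stopifnot(ncol(q) == ncol(k), nrow(k) == nrow(v))
  c_mat <- softmax_rows(q %*% t(k) / sqrt(d_k))
  # apply() drops to a vector when there is a single key; keep matrix shape
  if (!is.matrix(c_mat)) c_mat <- matrix(c_mat, nrow = nrow(q))
  list(C = c_mat, out = c_mat %*% v)
}

#' Cross-modal attention between two modalities
#'
#' Projects the first modality's tokens to queries and the second's to keys
#' and values with the shared maps, and attends:
#' `C = softmax(Q1 K2^T / sqrt(d_k))`, `F_12 = C V2`, aggregating modality-2
#' information into modality-1's token positions.
#'
#' @param f1,f2 token matrices (`n x d`).
#' @param params an [encoder_params].
#' @return list with `C` and `f_cross` (`n_1 x d`).
#' @export
cross_modal_attention <- function(f1, f2, params) {
  stopifnot(inherits(params, "encoder_params"))
  att <- scaled_dot_attention(f1 %*% params$w_q, f2 %*% params$w_k,
                              f2 %*% params$w_v, d_k = params$d_k)
  list(C = att$C, f_cross = att$out)
}

#' Fuse modalities with cross-modal attention, residual and refinement
#'
#' Computes (i) all pairwise cross-modal attention maps and attended
#' features; (ii) the fused vector `F_fused = sum_m C_m V_m`, where each
#' modality is attended by one learned global query token; (iii) the
#' residual `F_final = F_fused + sum_m meanpool(F_m)` which retains
#' modality-specific information (token sets of different cardinality are
#' mean-pooled to one d-vector so the sum is well-defined); and (iv) a
#' self-attention refinement of `F_final`.
#'
#' @param f_list named list of >= 2 token matrices (`n_m x d`).
#' @param params an [encoder_params].
#' @return an object of class `fused_representation` with fields
#'   `pairwise` (per ordered pair: `C`, `f_cross`), `modality_attention`
#'   (the global-query rows `C_m`), `f_fused`, `residual_sum`, `f_final`
#'   and `f_refined` (all `1 x d`).
#' @export
cross_modal_fuse <- function(f_list, params) {
  stopifnot(inherits(params, "encoder_params"))
  if (length(f_list) < 2L)
    af_stop("cross-modal fusion needs at least 2 modalities",
            class = "agrifusion_validation_error")
  mods <- names(f_list)
  if (is.null(mods)) mods <- paste0("m", seq_along(f_list))

  pairwise <- list()
  for (m1 in seq_along(f_list)) {
    for (m2 in seq_along(f_list)) {
      if (m1 == m2) next
      key <- paste0(mods[m1], "->", mods[m2])
      pairwise[[key]] <- cross_modal_attention(f_list[[m1]], f_list[[m2]],
                                               params)
    }
  }

  q_g <- params$global_query %*% params$w_q
  modality_attention <- list()
  f_fused <- matrix(0, 1L, params$d)
  for (m in seq_along(f_list)) {
    att <- scaled_dot_attention(q_g, f_list[[m]] %*% params$w_k,
                                f_list[[m]] %*% params$w_v,
                                d_k = params$d_k)
    modality_attention[[mods[m]]] <- att$C
    f_fused <- f_fused + att$out
  }

  residual_sum <- matrix(0, 1L, params$d)
  for (f in f_list) residual_sum <- residual_sum + colMeans(as.matrix(f))
  f_final <- f_fused + residual_sum

  refine <- scaled_dot_attention(f_final %*% params$w_q,
                                 f_final %*% params$w_k,
                                 f_final %*% params$w_v, d_k = params$d_k)

  structure(
    list(f_proj = f_list, pairwise = pairwise,
         modality_attention = modality_attention,
         f_fused = f_fused, residual_sum = residual_sum,
         f_final = f_final, f_refined = refine$out),
    class = "fused_representation"
  )
}

#' @export
print.fused_representation <- function(x, ...) {
  cat(sprintf("Fused representation: %d modalities, d = %d\n",
              length(x$f_proj), ncol(x$f_final)))
  cat(sprintf("  |F_fused| = %.4f, |F_final| = %.4f\n",
              sqrt(sum(x$f_fused^2)), sqrt(sum(x$f_final^2))))
  invisible(x)
}

# Sinusoidal positional encoding, T x d (0-based positions).
sinusoidal_positions <- function(t_len, d) {
  pos <- seq_len(t_len) - 1L
  out <- matrix(0, t_len, d)
  for (i in seq_len(d)) {
    angle <- pos / 10000^((2 * ((i - 1L) %/% 2)) / d)
    out[, i] <- if (i %% 2 == 1L) sin(angle) else cos(angle)
  }
  out
}

#' Aggregate a feature sequence over time
#'
#' Transformer mode (default): adds sinusoidal positional encodings, applies
#' one layer of self-attention with the shared projections, and returns the
#' last token's output — the unified spatiotemporal feature at the current
#' time. Recurrent mode: `h_t = tanh(W_h x_t + U_h h_{t-1} + b_h)` with
#' `h_0 = 0`, returning `h_T`; kept as the reference recurrent contract.
#'
#' @param x `T x d` matrix of per-step fused features (a list of d-vectors
#'   is accepted).
#' @param params an [encoder_params].
#' @param mode `"transformer"` (default) or `"recurrent"`.
#' @param positions logical; include positional encodings in transformer
#'   mode (default `TRUE`; without them the output is permutation-invariant
#'   in all but the final token).
#' @return a d-vector `G(t)`.
#' @export
temporal_aggregate <- function(x, params,
                               mode = c("transformer", "recurrent"),
                               positions = TRUE) {
  stopifnot(inherits(params, "encoder_params"))
  mode <- match.arg(mode)
  if (is.list(x)) x <- do.call(rbind, x)
  x <- as.matrix(x)
  if (nrow(x) == 0L)
    af_stop("temporal aggregation needs a nonempty sequence",
            class = "agrifusion_validation_error")
  if (ncol(x) != params$d)
    af_stop(sprintf("sequence feature dimension %d != d = %d",
                    ncol(x), params$d),
            class = "agrifusion_validation_error")
  if (mode == "recurrent") {
    r <- params$recurrent
    h <- rep(0, params$d)
    for (t in seq_len(nrow(x))) {
      h <- tanh(drop(r$w_h %*% x[t, ]) + drop(r$u_h %*% h) + r$b_h)
    }
    h
  } else {
    xe <- if (positions) x + sinusoidal_positions(nrow(x), params$d) else x
    att <- scaled_dot_attention(xe %*% params$w_q, xe %*% params$w_k,
                                xe %*% params$w_v, d_k = params$d_k)
    att$out[nrow(x), ]
  }
}
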