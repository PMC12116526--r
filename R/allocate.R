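# Priority-score computation and budget-proportional allocation with
# per-zone caps and surplus redistribution.

#' Per-zone assessment consumed by priority scoring
#'
#' @param H crop-health / stress index per zone (higher = worse condition,
#'   i.e. more need; detector anomaly scores plug in directly).
#' @param y_hat predicted yield per zone.
#' @param p `n x d_p` matrix of per-zone environmental variables.
#' @return an object of class `zone_assessment`.
#' @export
zone_assessment <- function(H, y_hat, p) {
  p <- as.matrix(p)
  n <- length(H)
  if (length(y_hat) != n || nrow(p) != n)
    af_stop("H, y_hat and p must agree on the number of zones",
            class = "agrifusion_validation_error")
  if (any(!is.finite(H)) || any(!is.finite(y_hat)) || any(!is.finite(p)))
    af_stop("assessment entries must be finite",
            class = "agrifusion_validation_error")
  structure(list(H = as.double(H), y_hat = as.double(y_hat), p = p),
            class = "zone_assessment")
}

#' Priority weights
#'
#' @param w_h,w_y scalar weights on crop health and predicted yield.
#' @param w_p d_p-vector of weights on the environmental variables.
#' @return an object of class `priority_weights`.
#' @export
priority_weights <- function(w_h = 1, w_y = 0, w_p = 0) {
  check_scalar(w_h, "w_h"); check_scalar(w_y, "w_y")
  if (any(!is.finite(w_p)))
    af_stop("field 'w_p' must be finite",
            class = "agrifusion_validation_error")
  structure(list(w_h = w_h, w_y = w_y, w_p = as.double(w_p)),
            class = "priority_weights")
}

#' Compute per-zone priority scores
#'
#' \deqn{r_i = w_h H_i + w_y \hat y_i + w_p^\top p_i.}
#' Higher scores mark zones needing more resources.
#'
#' @param assess a [zone_assessment].
#' @param weights a [priority_weights]; `w_p` must match the environmental
#'   dimension (a scalar 0 is accepted as "no environmental term").
#' @return numeric priority vector `r`.
#' @export
priority_scores <- function(assess, weights) {
  stopifnot(inherits(assess, "zone_assessment"),
            inherits(weights, "priority_weights"))
  w_p <- weights$w_p
  if (length(w_p) == 1L) w_p <- rep(w_p, ncol(assess$p))
  if (length(w_p) != ncol(assess$p))
    af_stop(sprintf("w_p has length %d but p has %d variables",
                    length(weights$w_p), ncol(assess$p)),
            class = "agrifusion_validation_error")
  weights$w_h * assess$H + weights$w_y * assess$y_hat +
    drop(assess$p %*% w_p)
}

#' Proportional allocation of one resource budget
#'
#' \deqn{u_i = \frac{r_i}{\sum_j r_j} B.} Negative scores are floored at 0
#' before the ratio (a zone cannot receive a negative amount). If no zone
#' has a positive score the call errors, or splits the budget uniformly
#' when `fallback = "uniform"`. The allocations sum to `B` exactly.
#'
#' @param r priority scores.
#' @param budget total budget `B >= 0`.
#' @param fallback `"error"` (default) or `"uniform"` for the all-
#'   nonpositive case.
#' @return allocation vector `u` with `sum(u) == B`.
#' @export
proportional_allocation <- function(r, budget,
                                    fallback = c("error", "uniform")) {
  fallback <- match.arg(fallback)
  check_scalar(budget, "budget", function(v) v >= 0, "nonnegative")
  r_pos <- pmax(r, 0)
  if (sum(r_pos) <= 0) {
    if (fallback == "uniform") return(rep(budget / length(r), length(r)))
    af_stop("all priority scores are <= 0; use fallback = \"uniform\" to split the budget evenly",
            class = "agrifusion_allocation_error")
  }
  r_pos / sum(r_pos) * budget
}

#' Cap allocations and redistribute the surplus
#'
#' Clips each zone to its cap and redistributes the clipped surplus
#' proportionally to the original scores among zones still below cap,
#' repeating until no surplus remains or every zone is capped (each pass
#' saturates at least one zone, so at most N passes run). On exit
#' `sum(u) == min(B, sum(caps))` and `u <= caps` elementwise; when
#' `sum(caps) < B` the unallocated remainder is attached as attribute
#' `"unallocated"`.
#'
#' @param u initial allocation (e.g. from [proportional_allocation()]).
#' @param caps per-zone caps (`>= 0`; `Inf` allowed).
#' @param budget the budget `B` that `u` was drawn from.
#' @param r scores used for redistribution shares (default `u`, which is
#'   proportional to the original scores).
#' @return adjusted allocation vector.
#' @export
cap_and_renormalize <- function(u, caps, budget, r = u) {
  n <- length(u)
  if (length(caps) != n || any(caps < 0))
    af_stop("caps must be nonnegative and match the allocation length",
            class = "agrifusion_validation_error")
  target <- min(budget, sum(caps))
  if (!is.finite(target)) target <- budget
  share <- pmax(r, 0)
  alloc <- pmin(u, caps)
  # an over-budget input (e.g. from an additive feedback update) is scaled
  # down proportionally first; scaling down cannot violate the caps
  if (sum(alloc) > target && sum(alloc) > 0)
    alloc <- alloc * (target / sum(alloc))
  for (pass in seq_len(n + 1L)) {
    deficit <- target - sum(alloc)
    if (deficit <= 1e-12 * max(1, target)) break
    open <- which(alloc < caps - 1e-15)
    if (length(open) == 0L) break
    w <- share[open]
    add <- if (sum(w) > 0) deficit * w / sum(w)
           else rep(deficit / length(open), length(open))
    alloc[open] <- pmin(alloc[open] + add, caps[open])
  }
  if (sum(caps) < budget) attr(alloc, "unallocated") <- budget - sum(caps)
  alloc
}
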