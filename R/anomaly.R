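# Gaussian normal model, anomaly scoring, threshold calibration and
# detection metrics.
#
# A zone is flagged when its feature vector deviates from the fitted model
# of normal crop condition: the score is the (Mahalanobis or Euclidean)
# distance from the normal mean, and a zone is anomalous when the score
# strictly exceeds the calibrated threshold tau. Under the Gaussian model
# the Mahalanobis score is a monotone transform of the negative
# log-likelihood, so thresholding the score and thresholding the likelihood
# are the same decision rule.

#' Fit the normal-condition model
#'
#' Estimates the mean and covariance of normal per-zone feature vectors,
#' with linear shrinkage of the sample covariance toward its diagonal:
#' `sigma = (1 - shrinkage) * S + shrinkage * diag(diag(S))`. Positive
#' definiteness is verified via Cholesky.
#'
#' @param x `n x d` matrix of feature vectors from normal zones.
#' @param shrinkage shrinkage weight in [0, 1] (default 0.1; small-sample
#'   stabilizer).
#' @param metric `"mahalanobis"` (default) or `"euclidean"`.
#' @return an object of class `normal_model` with fields `mu`, `sigma`,
#'   `sigma_inv`, `shrinkage`, `metric` and (after calibration) `tau`.
#' @export
fit_normal_model <- function(x, shrinkage = 0.1,
                             metric = c("mahalanobis", "euclidean")) {
  metric <- match.arg(metric)
  x <- as.matrix(x)
  if (nrow(x) < 2L)
    af_stop("need at least 2 normal samples to fit the model",
            class = "agrifusion_validation_error")
  check_scalar(shrinkage, "shrinkage", function(v) v >= 0 && v <= 1,
               "in [0, 1]")
  n <- nrow(x); d <- ncol(x)
  if (n <= d && shrinkage == 0)
    af_stop("n <= d with shrinkage 0: covariance is singular; increase shrinkage",
            class = "agrifusion_validation_error")
  mu <- colMeans(x)
  s <- stats::cov(x)
  sigma <- (1 - shrinkage) * s + shrinkage * diag(diag(s), d)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch))
    af_stop("covariance not positive-definite after shrinkage; try a larger shrinkage",
            class = "agrifusion_validation_error")
  structure(
    list(mu = mu, sigma = sigma, sigma_inv = chol2inv(ch),
         shrinkage = shrinkage, metric = metric, tau = NA_real_,
         n_fit = n),
    class = "normal_model"
  )
}

#' @export
print.normal_model <- function(x, ...) {
  cat(sprintf("Normal model: d = %d, metric = %s, shrinkage = %g, n = %d\n",
              length(x$mu), x$metric, x$shrinkage, x$n_fit))
  cat(sprintf("  tau = %s\n",
              if (is.na(x$tau)) "(uncalibrated)" else format(x$tau)))
  invisible(x)
}

#' Anomaly score of feature vectors
#'
#' Euclidean metric: \eqn{\|x - \mu\|_2}; Mahalanobis metric:
#' \eqn{\sqrt{(x-\mu)^\top \Sigma^{-1} (x-\mu)}}. Scores are nonnegative and
#' zero exactly at the mean.
#'
#' @param x a d-vector or an `n x d` matrix (one score per row).
#' @param model a fitted [fit_normal_model()].
#' @return numeric score(s) `>= 0`.
#' @export
anomaly_score <- function(x, model) {
  stopifnot(inherits(model, "normal_model"))
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != length(model$mu))
    af_stop(sprintf("feature dimension %d does not match model dimension %d",
                    ncol(x), length(model$mu)),
            class = "agrifusion_validation_error")
  if (model$metric == "euclidean") {
    dev <- sweep(x, 2L, model$mu)
    sqrt(rowSums(dev^2))
  } else {
    sqrt(stats::mahalanobis(x, model$mu, model$sigma_inv, inverted = TRUE))
  }
}

#' Calibrate the decision threshold from normal scores
#'
#' Sets tau to the empirical `q`-quantile (linear interpolation, R type 7)
#' of scores computed on held-out normal data, so the expected
#' false-positive rate on fresh normal zones is approximately `1 - q`.
#'
#' @param scores_normal nonempty numeric vector of scores on normal data.
#' @param q quantile in (0, 1).
#' @return the threshold tau.
#' @export
calibrate_threshold <- function(scores_normal, q = 0.95) {
  if (length(scores_normal) == 0L)
    af_stop("cannot calibrate a threshold from zero scores",
            class = "agrifusion_validation_error")
  check_scalar(q, "q", function(v) v > 0 && v < 1, "in (0, 1)")
  stats::quantile(scores_normal, probs = q, names = FALSE, type = 7)
}

#' Classify scores and (optionally) evaluate against truth
#'
#' A zone is labelled anomalous iff its score strictly exceeds `tau` (ties
#' count as normal). With ground truth supplied, computes accuracy,
#' precision, recall and F1. Degenerate 0/0 ratios are returned as 0 and
#' flagged in `undefined`.
#'
#' @param scores numeric score vector.
#' @param tau decision threshold.
#' @param truth optional logical/0-1 vector, `TRUE` = truly anomalous.
#' @return an object of class `detection_result` with `scores`, `labels`
#'   (`"anomalous"`/`"normal"`), and `metrics`/`confusion`/`undefined` when
#'   truth is given.
#' @export
classify_and_evaluate <- function(scores, tau, truth = NULL) {
  if (any(!is.finite(scores)))
    af_stop("scores must be finite", class = "agrifusion_validation_error")
  check_scalar(tau, "tau")
  flagged <- scores > tau
  labels <- ifelse(flagged, "anomalous", "normal")
  res <- list(scores = scores, tau = tau, labels = labels,
              metrics = NULL, confusion = NULL, undefined = character(0))
  if (!is.null(truth)) {
    if (length(truth) != length(scores))
      af_stop("truth length does not match scores",
              class = "agrifusion_validation_error")
    truth <- as.logical(truth)
    tp <- sum(flagged & truth); fp <- sum(flagged & !truth)
    fn <- sum(!flagged & truth); tn <- sum(!flagged & !truth)
    undef <- character(0)
    ratio <- function(num, den, name) {
      if (den == 0) { undef <<- c(undef, name); 0 } else num / den
    }
    precision <- ratio(tp, tp + fp, "precision")
    recall <- ratio(tp, tp + fn, "recall")
    f1 <- if (precision + recall == 0) {
      undef <- c(undef, "f1")
      0
    } else 2 * precision * recall / (precision + recall)
    res$metrics <- list(accuracy = (tp + tn) / length(scores),
                        precision = precision, recall = recall, f1 = f1)
    res$confusion <- c(tp = tp, fp = fp, fn = fn, tn = tn)
    res$undefined <- undef
  }
  structure(res, class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("Detection result: %d zones, %d flagged (tau = %g)\n",
              length(x$scores), sum(x$labels == "anomalous"), x$tau))
  if (!is.null(x$metrics)) {
    m <- x$metrics
    cat(sprintf("  accuracy %.3f  precision %.3f  recall %.3f  F1 %.3f\n",
                m$accuracy, m$precision, m$recall, m$f1))
    if (length(x$undefined))
      cat("  undefined (0/0, reported as 0):",
          paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}
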