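# Internal helpers shared across modules.

#' Numerically stable softmax
#'
#' @param x numeric vector of logits.
#' @return vector of the same length summing to 1.
#' @keywords internal
softmax <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1L)
  z <- exp(x - max(x))
  z / sum(z)
}

# Row-wise softmax of a matrix (each row sums to 1).
softmax_rows <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) == 1L) return(matrix(1, nrow(m), 1L))
  t(apply(m, 1L, softmax))
}

#' Derive a reproducible sub-stream seed
#'
#' All randomness in the package flows through one scenario- or call-level
#' seed; independent sub-streams (environment, weather, rendering, yield
#' noise, training) are derived with fixed documented offsets so that runs
#' are bit-reproducible and streams do not collide. The result always fits
#' in a 32-bit signed integer.
#'
#' @param seed base integer seed.
#' @param stream small integer identifying the consumer
#'   (1 = environment, 2 = weather, 3 = rendering, 4 = yield noise,
#'    5 = training, 6 = controller).
#' @param t time index or repetition counter, default 0.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stream, t = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  s <- (abs(as.double(seed)) %% 1000003) * 1009 +
    as.double(stream) * 7919 + as.double(t) * 104729
  as.integer(s %% 2147483587) + 1L
}

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Clip a numeric vector/matrix to [lo, hi] (either may be infinite).
clip <- function(x, lo = -Inf, hi = Inf) pmin(pmax(x, lo), hi)

# Abort with a classed error so callers/tests can match on the condition.
af_stop <- function(msg, class = "agrifusion_error", call. = FALSE) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Check that `x` is a numeric scalar satisfying predicate; otherwise error
# naming the offending field.
check_scalar <- function(x, name, ok = function(v) TRUE, what = "valid") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || !ok(x)) {
    af_stop(sprintf("field '%s' must be a finite %s scalar", name, what),
            class = "agrifusion_validation_error")
  }
  invisible(TRUE)
}

# FNV-1a 32-bit hash of a character string, returned as 8 hex digits.
# Used for config fingerprints in run manifests (no external digest
# dependency). Multiplication is carried out in split 16-bit halves to stay
# exact in double precision.
fnv1a_hash <- function(txt) {
  bytes <- as.integer(charToRaw(paste(txt, collapse = "")))
  h <- 2166136261
  prime <- 16777619
  two32 <- 4294967296
  for (b in bytes) {
    h <- bitwXor_dbl(h, b)
    lo <- (h %% 65536) * prime
    hi <- ((h %/% 65536) * prime) %% 65536
    h <- (lo + hi * 65536) %% two32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# XOR of a nonneg double < 2^32 with a byte, exact in doubles.
bitwXor_dbl <- function(h, b) {
  low <- h %% 256
  h - low + bitwXor(as.integer(low), as.integer(b))
}
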