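# Internal numerical helpers.

#' Log-sum-exp of a numeric vector
#' @param x numeric vector (may contain -Inf).
#' @return log(sum(exp(x))) computed stably.
#' @keywords internal
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)  # all -Inf (or contains Inf/NaN upstream)
  m + log(sum(exp(x - m)))
}

# Row-wise log-sum-exp of a matrix; stable against -Inf rows.
row_logsumexp <- function(a) {
  m <- do.call(pmax, as.data.frame(a))
  out <- m + log(rowSums(exp(a - m)))
  out[!is.finite(m)] <- m[!is.finite(m)]
  out
}

# Weighted quantile via the weighted empirical CDF (type-4-like interpolation).
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w))
  keep <- w > 0
  x <- x[keep]; w <- w[keep]
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  vapply(probs, function(p) {
    i <- which(cw >= p)[1]
    x[i]
  }, numeric(1))
}

weighted_median <- function(x, w) weighted_quantile(x, w, 0.5)

weighted_mean_sd <- function(x, w) {
  w <- w / sum(w)
  m <- sum(w * x)
  v <- sum(w * (x - m)^2)
  c(mean = m, sd = sqrt(v))
}

# Deterministic sub-seed for a pipeline stage; stays well below 2^31.
fan_seed <- function(seed, k) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(k)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
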