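# Event-based model core: sequence likelihood, greedy MAP search,
# Metropolis-Hastings over permutations, positional variance diagrams, and
# Kendall-tau sequence comparison.
#
# A sequence S is an integer permutation of 1..K (indices into the marker
# columns of an `ebm_likelihood` object). For a subject at unknown stage k,
# events S[1..k] have occurred; the model mixes uniformly over k = 0..K.

#' EBM sequence log-likelihood
#'
#' Sum over subjects of
#' `log( (1/(K+1)) * sum_{k=0}^{K} prod_{i<=k} p(x_S(i)|E) *
#' prod_{i>k} p(x_S(i)|not E) )`, computed in log space with log-sum-exp
#' over stages. Missing markers contribute a factor of 1 at every stage.
#'
#' @param s integer permutation of `1..K`.
#' @param mats an `ebm_likelihood` from [likelihood_matrices()].
#' @return Scalar log-likelihood.
#' @export
sequence_log_likelihood <- function(s, mats) {
  sum(stage_loglik_matrix(s, mats)$marginal)
}

# Shared core: per-row log p(x, stage = k | S) for k = 0..K (columns) and
# the per-row marginal log p(x | S) (uniform stage prior folded in).
stage_loglik_matrix <- function(s, mats) {
  k <- mats$K
  if (k == 0) stop("K = 0: no events")
  if (length(s) != k || !setequal(s, seq_len(k)))
    stop("`s` must be a permutation of 1..", k)
  le <- mats$log_e[, s, drop = FALSE]
  ln <- mats$log_not_e[, s, drop = FALSE]
  # matrix-product cumsums need finite entries (-Inf * 0 = NaN); a log
  # density of -700 already underflows to 0 on exp
  le[le < -700] <- -700
  ln[ln < -700] <- -700
  # cumulative sums along the sequence via an upper-triangular ones matrix
  tri <- upper.tri(matrix(0, k, k), diag = TRUE) * 1
  cum_e <- cbind(0, le %*% tri)
  cum_n <- cbind(0, ln %*% tri)
  tot_n <- cum_n[, k + 1]
  a <- cum_e + (tot_n - cum_n)       # n x (K+1): stage-k log products
  list(stage_loglik = a - log(k + 1),
       marginal = row_logsumexp(a) - log(k + 1))
}

#' Greedy ascent over pairwise position swaps
#'
#' From each random start, evaluates all `K(K-1)/2` pairwise position swaps
#' and accepts the best strictly-improving one, until no swap improves
#' (equal-likelihood swaps are rejected, keeping the search deterministic
#' given the seed). Returns the best sequence over starts.
#'
#' @param mats an `ebm_likelihood`.
#' @param n_starts number of random restarts.
#' @param seed integer seed.
#' @return List with `sequence`, `log_lik`, `n_starts`.
#' @export
greedy_ascent <- function(mats, n_starts = 16, seed = 1L) {
  stopifnot(n_starts >= 1)
  set.seed(seed)
  k <- mats$K
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  best_s <- NULL
  best_ll <- -Inf
  for (st in seq_len(n_starts)) {
    s <- if (k > 1) sample.int(k) else 1L
    ll <- sequence_log_likelihood(s, mats)
    repeat {
      cand_ll <- -Inf
      cand_s <- NULL
      for (p in seq_len(nrow(pairs))) {
        s2 <- s
        s2[c(pairs[p, 1], pairs[p, 2])] <- s2[c(pairs[p, 2], pairs[p, 1])]
        ll2 <- sequence_log_likelihood(s2, mats)
        if (ll2 > cand_ll) { cand_ll <- ll2; cand_s <- s2 }
      }
      if (is.null(cand_s) || cand_ll <= ll) break
      s <- cand_s; ll <- cand_ll
    }
    if (ll > best_ll) { best_ll <- ll; best_s <- s }
  }
  list(sequence = best_s, log_lik = best_ll, n_starts = n_starts)
}

#' Metropolis-Hastings sampling of the sequence posterior
#'
#' Symmetric proposal: swap two uniformly chosen positions; acceptance
#' `min(1, exp(delta log-likelihood))` (uniform prior over sequences).
#' Post-burn-in samples are retained; the MAP is the best sequence seen
#' anywhere in the chain (including the initial state).
#'
#' @param mats an `ebm_likelihood`.
#' @param init initial sequence (e.g. the greedy result).
#' @param n_iter total iterations.
#' @param burn_in iterations discarded from the front.
#' @param seed integer seed.
#' @return Object of class `ebm_posterior`: `samples` (matrix, one retained
#'   sequence per row), `log_liks`, `map`, `map_log_lik`, `accept_rate`,
#'   `settings`.
#' @export
mcmc_sample <- function(mats, init, n_iter = 100000, burn_in = 50000,
                        seed = 1L) {
  stopifnot(n_iter > burn_in, burn_in >= 0)
  set.seed(seed)
  k <- mats$K
  s <- as.integer(init)
  ll <- sequence_log_likelihood(s, mats)
  map_s <- s; map_ll <- ll
  n_keep <- n_iter - burn_in
  samples <- matrix(NA_integer_, n_keep, k)
  log_liks <- numeric(n_keep)
  n_acc <- 0L
  for (it in seq_len(n_iter)) {
    if (k > 1) {
      ij <- sample.int(k, 2)
      s2 <- s
      s2[ij] <- s2[rev(ij)]
      ll2 <- sequence_log_likelihood(s2, mats)
      if (log(runif(1)) < ll2 - ll) {
        s <- s2; ll <- ll2; n_acc <- n_acc + 1L
        if (ll > map_ll) { map_ll <- ll; map_s <- s }
      }
    }
    if (it > burn_in) {
      samples[it - burn_in, ] <- s
      log_liks[it - burn_in] <- ll
    }
  }
  structure(list(samples = samples, log_liks = log_liks, map = map_s,
                 map_log_lik = map_ll, accept_rate = n_acc / n_iter,
                 settings = list(n_iter = n_iter, burn_in = burn_in,
                                 seed = seed, init = as.integer(init)),
                 markers = mats$markers),
            class = "ebm_posterior")
}

#' Positional variance matrix
#'
#' `P[i, j]` = fraction of posterior samples placing event `i` at sequence
#' position `j`; doubly stochastic by construction. Rendered as a heatmap
#' this is the positional variance diagram.
#'
#' @param samples matrix of sampled sequences (one per row) or an
#'   `ebm_posterior`.
#' @param markers optional marker names for the rows.
#' @return K x K matrix, rows = events, columns = positions.
#' @export
positional_variance <- function(samples, markers = NULL) {
  if (inherits(samples, "ebm_posterior")) {
    markers <- markers %||% samples$markers
    samples <- samples$samples
  }
  if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1)
  if (nrow(samples) == 0) stop("no samples")
  k <- ncol(samples)
  p <- matrix(0, k, k)
  for (j in seq_len(k)) {             # position j holds event samples[, j]
    tab <- tabulate(samples[, j], nbins = k)
    p[, j] <- tab / nrow(samples)
  }
  rownames(p) <- markers %||% paste0("event", seq_len(k))
  colnames(p) <- paste0("pos", seq_len(k))
  p
}

#' Kendall's tau between two event sequences
#'
#' Counts discordant pairs d between the orderings and returns the rank
#' correlation `tau = 1 - 4 d / (K (K - 1))` (1 identical, -1 reversed).
#' `method = "distance"` instead returns the normalized Kendall tau
#' distance `d / (K (K - 1) / 2)` in `[0, 1]`.
#'
#' @param a,b sequences over the same event set (any atomic type).
#' @param method `"correlation"` (default) or `"distance"`.
#' @return Scalar in `[-1, 1]` (correlation) or `[0, 1]` (distance).
#' @export
kendall_tau <- function(a, b, method = c("correlation", "distance")) {
  method <- match.arg(method)
  if (length(a) != length(b)) stop("sequences differ in length")
  if (!setequal(a, b)) stop("sequences are over different event sets")
  k <- length(a)
  if (k < 2) return(if (method == "correlation") 1 else 0)
  pos_b <- match(a, b)                # b-positions in a's order
  d <- 0L
  for (i in seq_len(k - 1)) {
    d <- d + sum(pos_b[(i + 1):k] < pos_b[i])
  }
  if (method == "correlation") 1 - 4 * d / (k * (k - 1)) else d / (k * (k - 1) / 2)
}
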