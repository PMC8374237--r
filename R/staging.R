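# Per-subject-visit staging under a fixed event sequence.
#
# Given the fitted mixtures and a sequence S, the stage posterior is
# p(k) proportional to prod_{i<=k} p(x_S(i)|E) * prod_{i>k} p(x_S(i)|not E),
# normalized over k = 0..K; each visit is staged independently.

#' Stage posteriors for every row of a likelihood object
#'
#' @param mats an `ebm_likelihood` (see [likelihood_matrices()]).
#' @param s fixed event sequence (typically the MAP sequence).
#' @return Matrix of dimension rows x (K+1); row `r`, column `k+1` is the
#'   posterior probability that row `r` is at stage `k`. Rows with every
#'   marker missing get a uniform posterior with a warning.
#' @export
stage_posteriors <- function(mats, s) {
  sl <- stage_loglik_matrix(s, mats)$stage_loglik
  p <- exp(sl - row_logsumexp(sl))
  all_missing <- rowSums(!mats$missing) == 0
  if (any(all_missing)) {
    warning(sum(all_missing), " row(s) with all markers missing: uniform posterior")
    p[all_missing, ] <- 1 / (mats$K + 1)
  }
  colnames(p) <- paste0("stage", 0:mats$K)
  p
}

#' Maximum-likelihood stage
#'
#' Smallest argmax of the posterior (ties broken toward the lower,
#' more conservative stage).
#'
#' @param p posterior matrix from [stage_posteriors()] (or a single
#'   posterior vector).
#' @return Integer vector of ML stages in `0..K`.
#' @export
ml_stage <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  apply(p, 1, which.max) - 1L
}

#' Expected (weighted-average) stage
#'
#' `sum_k k * p(k)`; a continuous stage measure that accommodates staging
#' uncertainty.
#'
#' @param p posterior matrix or vector.
#' @return Numeric vector of expected stages.
#' @export
expected_stage <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  drop(p %*% (seq_len(ncol(p)) - 1))
}

#' Stage every subject-visit of a table
#'
#' Convenience wrapper: builds likelihood matrices from the fits, computes
#' stage posteriors under `s`, and returns the row metadata with `ml_stage`
#' and `expected_stage` columns (posterior matrix attached as attribute
#' `"posterior"`).
#'
#' @param fits named list of `kde_mixture_fit`s.
#' @param table adjusted biomarker table (all visits).
#' @param s event sequence.
#' @param markers marker column names.
#' @return Data frame of staged rows.
#' @export
stage_table <- function(fits, table, s, markers = names(fits)) {
  mats <- likelihood_matrices(fits, table, markers)
  p <- stage_posteriors(mats, s)
  out <- cbind(mats$meta,
               ml_stage = ml_stage(p),
               expected_stage = expected_stage(p))
  attr(out, "posterior") <- p
  out
}
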