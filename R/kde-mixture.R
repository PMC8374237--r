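# Two-component KDE mixture models of healthy vs abnormal biomarker
# distributions. The two component densities are weighted Gaussian kernel
# density estimates, re-weighted by EM-style responsibilities; this is more
# flexible than a two-Gaussian mixture and tolerates skewed markers.

#' Weighted Gaussian kernel density estimate
#'
#' Support points with responsibilities as weights; bandwidth by Silverman's
#' rule of thumb on the weighted sample, using the effective sample size
#' `1 / sum(w^2)` (normalized weights).
#'
#' @param x support points.
#' @param w nonnegative weights (need not sum to 1).
#' @param bw optional fixed bandwidth; default Silverman.
#' @return List of class `weighted_kde` with `support`, `weights`
#'   (normalized), `bw`.
#' @export
weighted_kde <- function(x, w = rep(1, length(x)), bw = NULL) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  keep <- w > 0 & is.finite(x)
  x <- x[keep]; w <- w[keep]
  w <- w / sum(w)
  if (is.null(bw)) {
    n_eff <- 1 / sum(w^2)
    ms <- weighted_mean_sd(x, w)
    iqr <- diff(weighted_quantile(x, w, c(0.25, 0.75)))
    a <- min(ms["sd"], iqr / 1.349)
    if (!is.finite(a) || a <= 0) a <- max(ms["sd"], 1e-8)
    bw <- 0.9 * a * n_eff^(-1 / 5)
  }
  structure(list(support = x, weights = w, bw = unname(bw)),
            class = "weighted_kde")
}

#' Evaluate a weighted KDE
#' @param kde a `weighted_kde`.
#' @param q query points.
#' @param chunk evaluate in chunks of this many query points to bound memory.
#' @return Density values at `q`.
#' @export
kde_eval <- function(kde, q, chunk = 5000L) {
  out <- numeric(length(q))
  n <- length(q)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    d <- outer(q[s:e], kde$support, "-")
    out[s:e] <- drop(dnorm(d, sd = kde$bw) %*% kde$weights)
  }
  out
}

#' Fit a two-component KDE mixture to one biomarker
#'
#' Alternating (EM-style) fit of normal and abnormal weighted-KDE components
#' on adjusted, oriented values (larger = more abnormal). Responsibilities
#' are initialized from clinical labels: control rows are anchored to the
#' normal component throughout; patient rows start split by the threshold
#' control median + 1 control SD. Each iteration re-estimates both weighted
#' KDEs (Silverman bandwidth recomputed), updates the abnormal mixing
#' fraction, recomputes the patients' posterior responsibilities under the
#' current components, projects them onto functions monotone non-decreasing
#' in the marker value (the model's monotone-abnormality assumption), and
#' re-assigns patients to the component with the larger responsibility.
#' Hard assignment during iteration keeps the two nonparametric components
#' on disjoint supports, which is what makes the KDE mixture identifiable —
#' with soft weights an unconstrained KDE component can absorb the entire
#' bimodal marginal. Iteration stops when the mean absolute responsibility
#' change drops below `tol` or `max_iter` is reached. If the fitted
#' abnormal component ends up below the normal one (weighted medians), the
#' components are swapped. The returned responsibilities are the final soft
#' (monotone-projected) posteriors.
#'
#' @param values numeric vector of adjusted marker values.
#' @param labels character/factor vector, `"control"` or `"patient"`,
#'   same length as `values`.
#' @param max_iter maximum iterations.
#' @param tol convergence tolerance on mean absolute responsibility change.
#' @param density_floor lower bound applied when evaluating component
#'   densities (guards against -Inf log-likelihoods far outside support).
#' @return Object of class `kde_mixture_fit`: `normal`, `abnormal`
#'   (weighted KDEs), `pi_abnormal` (mean responsibility over all rows),
#'   `responsibilities`, `iterations`, `converged`, `swapped`,
#'   `density_floor`.
#' @export
fit_kde_mixture <- function(values, labels, max_iter = 200, tol = 1e-4,
                            density_floor = 1e-12) {
  keep <- is.finite(values)
  x <- values[keep]
  lab <- as.character(labels)[keep]
  if (!all(lab %in% c("control", "patient")))
    stop("labels must be 'control' or 'patient'")
  ctrl <- lab == "control"
  pat <- !ctrl
  if (sum(ctrl) < 10)
    stop("need at least 10 finite control values")
  if (length(unique(x)) == 1) stop("degenerate input: all values identical")

  thr <- median(x[ctrl]) + sd(x[ctrl])
  r <- numeric(length(x))
  r[pat] <- as.numeric(x[pat] > thr)

  fit_abnormal_tail <- function() {
    # degenerate path: no abnormal mass; anchor the abnormal component to
    # the upper tail so densities remain evaluable
    tail_pts <- x[x > thr]
    if (length(tail_pts) < 2)
      tail_pts <- sort(x, decreasing = TRUE)[1:max(2, length(x) %/% 10)]
    weighted_kde(tail_pts)
  }
  fit_components <- function(r) {
    kn <- weighted_kde(x, 1 - r)
    ka <- if (sum(r) > 1e-8) weighted_kde(x, r) else fit_abnormal_tail()
    list(kn = kn, ka = ka)
  }
  # patients' posterior P(abnormal | x), monotone in x
  soft_resp <- function(cmp, r) {
    p <- min(max(mean(r[pat]), 1e-6), 1 - 1e-6)
    fn <- pmax(kde_eval(cmp$kn, x[pat]), density_floor)
    fa <- pmax(kde_eval(cmp$ka, x[pat]), density_floor)
    s <- p * fa / (p * fa + (1 - p) * fn)
    o <- order(x[pat])
    s[o] <- stats::isoreg(x[pat][o], s[o])$yf
    pmin(pmax(s, 0), 1)
  }

  cmp <- fit_components(r)
  converged <- !any(pat)
  it <- 0
  while (!converged && it < max_iter) {
    it <- it + 1
    s <- soft_resp(cmp, r)
    r_new <- r
    r_new[pat] <- as.numeric(s > 0.5)
    delta <- mean(abs(r_new - r))
    r <- r_new
    cmp <- fit_components(r)
    if (delta < tol) converged <- TRUE
  }
  if (!converged)
    warning("KDE mixture did not converge in ", max_iter,
            " iterations; returning last iterate")
  if (any(pat)) r[pat] <- soft_resp(cmp, r)
  kn <- cmp$kn
  ka <- cmp$ka
  pi_ab <- mean(r)

  swapped <- FALSE
  if (weighted_median(ka$support, ka$weights) <
      weighted_median(kn$support, kn$weights)) {
    tmp <- kn; kn <- ka; ka <- tmp
    r <- 1 - r
    pi_ab <- mean(r)
    swapped <- TRUE
  }
  structure(list(normal = kn, abnormal = ka, pi_abnormal = pi_ab,
                 responsibilities = r, labels = lab, values = x,
                 iterations = it, converged = converged, swapped = swapped,
                 density_floor = density_floor),
            class = "kde_mixture_fit")
}

#' Evaluate both mixture components
#' @param fit a `kde_mixture_fit`.
#' @param x query values (vectorized).
#' @return List with `p_normal` and `p_abnormal`, each floored at the fit's
#'   density floor.
#' @export
eval_components <- function(fit, x) {
  list(p_normal = pmax(kde_eval(fit$normal, x), fit$density_floor),
       p_abnormal = pmax(kde_eval(fit$abnormal, x), fit$density_floor))
}

#' Fit mixtures for every marker of a reference cohort
#'
#' Controls are the cohort's baseline HC rows, patients its baseline HD rows
#' (the groups that best sample the healthy and abnormal ends).
#'
#' @param table adjusted biomarker table.
#' @param markers marker column names.
#' @param cohort reference cohort name (default: all rows).
#' @param baseline_visit baseline visit index.
#' @param ... passed to [fit_kde_mixture()].
#' @return Named list of `kde_mixture_fit` objects.
#' @export
fit_all_mixtures <- function(table, markers, cohort = NULL,
                             baseline_visit = 1, ...) {
  sub <- table[table$visit == baseline_visit, , drop = FALSE]
  if (!is.null(cohort)) sub <- sub[sub$cohort == cohort, , drop = FALSE]
  sub <- sub[sub$group %in% c("HC", "HD"), , drop = FALSE]
  lab <- ifelse(sub$group == "HC", "control", "patient")
  fits <- lapply(markers, function(m) fit_kde_mixture(sub[[m]], lab, ...))
  names(fits) <- markers
  fits
}

#' Precompute per-row log-density matrices for the EBM likelihood
#'
#' @param fits named list of `kde_mixture_fit`s covering every marker.
#' @param table adjusted biomarker table.
#' @param markers marker column names (order defines event indices).
#' @return Object of class `ebm_likelihood`: `log_e` and `log_not_e`
#'   (rows x markers, log p(x|E) and log p(x|not E), floored), `missing`
#'   (logical matrix; missing cells carry 0 in both log matrices so they
#'   contribute a factor of 1 at every stage), `meta` (row metadata),
#'   `markers`, `K`.
#' @export
likelihood_matrices <- function(fits, table, markers = names(fits)) {
  miss_fit <- setdiff(markers, names(fits))
  if (length(miss_fit))
    stop("no mixture fit for marker(s): ", paste(miss_fit, collapse = ", "))
  n <- nrow(table)
  k <- length(markers)
  log_e <- log_not_e <- matrix(0, n, k, dimnames = list(NULL, markers))
  missing <- matrix(FALSE, n, k, dimnames = list(NULL, markers))
  for (j in seq_len(k)) {
    x <- table[[markers[j]]]
    na <- !is.finite(x)
    missing[, j] <- na
    if (all(na)) next
    d <- eval_components(fits[[markers[j]]], x[!na])
    log_e[!na, j] <- log(d$p_abnormal)
    log_not_e[!na, j] <- log(d$p_normal)
  }
  meta_cols <- intersect(c("subject_id", "cohort", "visit", "group", "age",
                           "sex", "cag"), names(table))
  structure(list(log_e = log_e, log_not_e = log_not_e, missing = missing,
                 meta = table[, meta_cols, drop = FALSE],
                 markers = markers, K = k),
            class = "ebm_likelihood")
}

#' Serialize / restore a KDE mixture fit as JSON
#' @param fit a `kde_mixture_fit` (or named list of them for `mixtures_to_json`).
#' @param path file path.
#' @return `read_mixtures` returns the named list of fits.
#' @export
write_mixtures <- function(fit, path) {
  strip <- function(f) {
    out <- f[c("normal", "abnormal", "pi_abnormal", "iterations",
               "converged", "swapped", "density_floor")]
    out$normal <- unclass(out$normal)
    out$abnormal <- unclass(out$abnormal)
    out
  }
  obj <- if (inherits(fit, "kde_mixture_fit")) list(fit = strip(fit)) else lapply(fit, strip)
  # 17 significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_mixtures
#' @export
read_mixtures <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(obj, function(f) {
    f$normal <- structure(list(support = f$normal$support,
                               weights = f$normal$weights,
                               bw = f$normal$bw), class = "weighted_kde")
    f$abnormal <- structure(list(support = f$abnormal$support,
                                 weights = f$abnormal$weights,
                                 bw = f$abnormal$bw), class = "weighted_kde")
    structure(f, class = "kde_mixture_fit")
  })
}
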