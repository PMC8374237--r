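# CAG-stratified polynomial mixed-effects models of EBM stage vs age,
# degree selection by confidence-band width, and age-at-stage prediction.

#' Fit a polynomial mixed-effects model of stage on age
#'
#' `stage ~ age + age^2 (degree 2) + (1 | subject)`, restricted maximum
#' likelihood via lme4. The response is the expected (continuous) stage.
#' Falls back to an ordinary least-squares fit (random-intercept variance 0)
#' when the mixed fit fails, e.g. on noise-free data with no residual
#' variance.
#'
#' @param data data.frame with columns `subject_id`, `age`, `stage`.
#' @param degree polynomial degree, 1 or 2.
#' @param cag_group optional integer label carried through to the fit.
#' @param band_points number of ages at which the confidence band is
#'   evaluated.
#' @return Object of class `progression_fit`: `degree`, `beta` (raw
#'   polynomial coefficients, intercept first), `vcov`, `sigma2` (residual
#'   variance), `tau2` (random-intercept variance), `n_subjects`, `n_obs`,
#'   `age_range`, `band` (data.frame age/fit/lwr/upr), `mean_band_width`,
#'   `cag_group`.
#' @export
fit_mixed_model <- function(data, degree = 1, cag_group = NA_integer_,
                            band_points = 50) {
  stopifnot(degree %in% c(1, 2))
  data <- data[is.finite(data$age) & is.finite(data$stage), , drop = FALSE]
  nv <- table(data$subject_id)
  if (sum(nv >= 2) < 3)
    stop("need >= 3 subjects with >= 2 visits (have ", sum(nv >= 2), ")")

  form <- if (degree == 1) {
    stage ~ age + (1 | subject_id)
  } else {
    stage ~ age + I(age^2) + (1 | subject_id)
  }
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(form, data = data, REML = TRUE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))
    )),
    error = function(e) NULL)
  if (!is.null(fit)) {
    beta <- lme4::fixef(fit)
    vc <- as.matrix(vcov(fit))
    sigma2 <- unname(stats::sigma(fit)^2)
    tau2 <- unname(as.data.frame(lme4::VarCorr(fit))$vcov[1])
  } else {
    # degenerate fallback: pooled OLS, zero random-intercept variance
    lf <- if (degree == 1) lm(stage ~ age, data = data) else lm(stage ~ age + I(age^2), data = data)
    beta <- coef(lf)
    vc <- vcov(lf)
    vc[!is.finite(vc)] <- 0
    sigma2 <- max(summary(lf)$sigma^2, 0)
    tau2 <- 0
    warning("mixed model failed; ordinary least-squares fallback used")
  }
  ar <- range(data$age)
  grid <- seq(ar[1], ar[2], length.out = band_points)
  x <- if (degree == 1) cbind(1, grid) else cbind(1, grid, grid^2)
  pred <- drop(x %*% beta)
  se <- sqrt(pmax(rowSums((x %*% vc) * x), 0))
  band <- data.frame(age = grid, fit = pred,
                     lwr = pred - 1.96 * se, upr = pred + 1.96 * se)
  structure(list(degree = degree, beta = unname(beta), vcov = unname(vc),
                 sigma2 = sigma2, tau2 = tau2,
                 n_subjects = length(nv), n_obs = nrow(data),
                 age_range = ar, band = band,
                 mean_band_width = mean(band$upr - band$lwr),
                 cag_group = cag_group),
            class = "progression_fit")
}

#' Select between linear and quadratic fits
#'
#' Picks the fit whose fitted mean curve has the smaller average 95%
#' confidence-band width over the observed ages; ties (and equal fits) go
#' to the lower degree.
#'
#' @param fit1,fit2 `progression_fit`s of the same data at degrees 1 and 2.
#' @return The selected `progression_fit`.
#' @export
select_model <- function(fit1, fit2) {
  if (fit1$mean_band_width <= fit2$mean_band_width) fit1 else fit2
}

#' Age at which the fitted mean curve reaches a target stage
#'
#' Solves `fitted_mean(age) = target_stage` for the smallest real root;
#' uncertainty from a seeded parametric bootstrap of the fixed-effect
#' coefficients (multivariate normal draws from the estimated covariance,
#' 2.5/97.5 percentiles of the per-draw root).
#'
#' @param fit a `progression_fit`.
#' @param target_stage stage to reach (e.g. 5 for motor-score abnormality).
#' @param n_boot bootstrap draws.
#' @param seed integer seed.
#' @param window how far (years) beyond the observed age range a root may
#'   lie before it is declared not reached.
#' @return List: `age`, `lower`, `upper`, `reached`, `extrapolated`.
#' @export
age_at_stage <- function(fit, target_stage, n_boot = 1000, seed = 1L,
                         window = 10) {
  lo <- fit$age_range[1] - window
  hi <- fit$age_range[2] + window
  root <- function(beta) {
    r <- if (length(beta) == 2) {
      if (beta[2] == 0) numeric(0) else (target_stage - beta[1]) / beta[2]
    } else {
      disc <- beta[2]^2 - 4 * beta[3] * (beta[1] - target_stage)
      if (beta[3] == 0) {
        if (beta[2] == 0) numeric(0) else (target_stage - beta[1]) / beta[2]
      } else if (disc < 0) numeric(0) else {
        (-beta[2] + c(-1, 1) * sqrt(disc)) / (2 * beta[3])
      }
    }
    r <- r[r >= lo & r <= hi]
    if (length(r) == 0) NA_real_ else min(r)
  }
  est <- root(fit$beta)
  if (is.na(est)) {
    return(list(age = NA_real_, lower = NA_real_, upper = NA_real_,
                reached = FALSE, extrapolated = NA))
  }
  set.seed(seed)
  draws <- MASS::mvrnorm(n_boot, fit$beta, fit$vcov)
  boots <- apply(draws, 1, root)
  boots <- boots[is.finite(boots)]
  ci <- if (length(boots) >= 10) quantile(boots, c(0.025, 0.975), names = FALSE)
        else c(NA_real_, NA_real_)
  list(age = est, lower = ci[1], upper = ci[2], reached = TRUE,
       extrapolated = est < fit$age_range[1] || est > fit$age_range[2])
}

#' Fit progression models per CAG repeat length
#'
#' Filters to gene-carrier rows with at least one follow-up visit, fits
#' degree-1 and degree-2 models per integer CAG group, and selects per group
#' via [select_model()]. Groups with fewer than `min_subjects` qualifying
#' subjects are skipped with a warning.
#'
#' @param staged staged table with columns `subject_id`, `age`, `cag`,
#'   `expected_stage` (and one row per visit).
#' @param min_subjects minimum subjects (with >= 2 visits) per CAG group.
#' @return Named list (by CAG) of selected `progression_fit`s.
#' @export
fit_progression_by_cag <- function(staged, min_subjects = 3) {
  d <- staged[is.finite(staged$cag), , drop = FALSE]
  d <- data.frame(subject_id = d$subject_id, age = d$age, cag = d$cag,
                  stage = d$expected_stage, stringsAsFactors = FALSE)
  out <- list()
  for (cg in sort(unique(d$cag))) {
    dg <- d[d$cag == cg, , drop = FALSE]
    nv <- table(dg$subject_id)
    dg <- dg[dg$subject_id %in% names(nv)[nv >= 2], , drop = FALSE]
    if (length(unique(dg$subject_id)) < min_subjects) {
      warning("CAG ", cg, ": fewer than ", min_subjects,
              " subjects with follow-up; skipped")
      next
    }
    f1 <- fit_mixed_model(dg, degree = 1, cag_group = cg)
    f2 <- tryCatch(fit_mixed_model(dg, degree = 2, cag_group = cg),
                   error = function(e) NULL)
    out[[as.character(cg)]] <- if (is.null(f2)) f1 else select_model(f1, f2)
  }
  out
}
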