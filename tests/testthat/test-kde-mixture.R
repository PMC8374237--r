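test_that("well-separated samples give the right mixing fraction and shapes", {
  set.seed(41)
  x <- c(rnorm(200, 0, 1), rnorm(100, 4, 1))
  lab <- rep(c("control", "patient"), c(200, 100))
  fit <- fit_kde_mixture(x, lab)
  expect_true(fit$converged)
  expect_lt(abs(fit$pi_abnormal - 100 / 300), 0.05)
  # medians ordered
  expect_gt(hdebm:::weighted_median(fit$abnormal$support, fit$abnormal$weights),
            hdebm:::weighted_median(fit$normal$support, fit$normal$weights))
  # both densities integrate to 1 (trapezoid quadrature oracle)
  g <- seq(-10, 14, length.out = 4001)
  for (cmp in c("normal", "abnormal")) {
    d <- kde_eval(fit[[cmp]], g)
    expect_equal(sum((d[-1] + d[-length(d)]) / 2 * diff(g)), 1,
                 tolerance = 1e-3)
  }
})

test_that("an all-control unimodal sample leaves almost no abnormal mass", {
  set.seed(43)
  x <- rnorm(150)
  fit <- fit_kde_mixture(x, rep("control", 150))
  expect_lte(fit$pi_abnormal, 0.1)
  expect_error(fit_kde_mixture(rep(1, 50), rep("control", 50)), "degenerate")
  expect_error(fit_kde_mixture(rnorm(5), rep("control", 5)), "at least 10")
})

test_that("component evaluation: mode dominance, symmetry, density floor", {
  set.seed(47)
  x <- c(rnorm(300, 0, 1), rnorm(300, 4, 1))
  lab <- rep(c("control", "patient"), each = 300)
  fit <- fit_kde_mixture(x, lab)
  d0 <- eval_components(fit, 0)
  expect_gt(d0$p_normal, d0$p_abnormal)
  d4 <- eval_components(fit, 4)
  expect_gt(d4$p_abnormal, d4$p_normal)
  # an exactly mirror-symmetric fit evaluates symmetrically at the midpoint
  xs <- rnorm(200)
  sym <- structure(list(normal = weighted_kde(xs),
                        abnormal = weighted_kde(4 - xs),
                        pi_abnormal = 0.5, density_floor = 1e-12),
                   class = "kde_mixture_fit")
  dm <- eval_components(sym, 2)
  expect_lt(abs(dm$p_normal - dm$p_abnormal) /
              max(dm$p_normal, dm$p_abnormal), 0.05)
  far <- eval_components(fit, 1e6)
  expect_equal(far$p_normal, 1e-12)
  expect_equal(far$p_abnormal, 1e-12)
})

test_that("responsibilities track the two-Gaussian oracle posterior", {
  set.seed(53)
  n_pat <- 250
  x <- c(rnorm(250, 0, 1), rnorm(n_pat / 2, 0, 1), rnorm(n_pat / 2, 2, 1))
  lab <- rep(c("control", "patient"), c(250, n_pat))
  fit <- fit_kde_mixture(x, lab)
  xp <- fit$values[fit$labels == "patient"]
  oracle <- 0.5 * dnorm(xp, 2) / (0.5 * dnorm(xp, 2) + 0.5 * dnorm(xp, 0))
  got <- fit$responsibilities[fit$labels == "patient"]
  expect_lt(mean(abs(got - oracle)), 0.1)
})

test_that("the fit is invariant to permuting the input sample", {
  set.seed(59)
  x <- c(rnorm(100, 0, 1), rnorm(80, 3, 1))
  lab <- rep(c("control", "patient"), c(100, 80))
  f1 <- fit_kde_mixture(x, lab)
  o <- sample(length(x))
  f2 <- fit_kde_mixture(x[o], lab[o])
  expect_equal(f1$pi_abnormal, f2$pi_abnormal, tolerance = 1e-12)
  g <- seq(-4, 7, length.out = 101)
  expect_equal(kde_eval(f1$normal, g), kde_eval(f2$normal, g),
               tolerance = 1e-10)
  expect_equal(kde_eval(f1$abnormal, g), kde_eval(f2$abnormal, g),
               tolerance = 1e-10)
})

test_that("likelihood matrices honour their contract and survive serialization", {
  set.seed(61)
  x <- c(rnorm(50), rnorm(50, 3))
  lab <- rep(c("control", "patient"), each = 50)
  fits <- list(mA = fit_kde_mixture(x, lab), mB = fit_kde_mixture(x + 1, lab))
  tab <- data.frame(subject_id = c("s1", "s2"), cohort = "X",
                    visit = 1, group = "PreHD", age = 40, sex = 0,
                    cag = 42, mA = c(1.5, NA), mB = c(0.2, 2.5))
  mats <- likelihood_matrices(fits, tab)
  d <- eval_components(fits$mA, 1.5)
  expect_equal(unname(mats$log_e[1, "mA"]), log(d$p_abnormal))
  expect_equal(unname(mats$log_not_e[1, "mA"]), log(d$p_normal))
  expect_true(mats$missing[2, "mA"])
  expect_identical(unname(mats$log_e[2, "mA"]), 0)
  expect_identical(unname(mats$log_not_e[2, "mA"]), 0)
  expect_error(likelihood_matrices(fits, tab, markers = c("mA", "mC")), "mC")

  # round trip through JSON reproduces the matrices bit-identically
  path <- withr::local_tempfile(fileext = ".json")
  write_mixtures(fits, path)
  fits2 <- read_mixtures(path)
  mats2 <- likelihood_matrices(fits2, tab)
  expect_identical(mats$log_e, mats2$log_e)
  expect_identical(mats$log_not_e, mats2$log_not_e)
})

test_that("mixtures transfer across cohorts with shared generative parameters", {
  nm <- default_markers()$name
  specs <- list(
    list(name = "A", n_HC = 150L, n_PreHD = 150L, n_HD = 150L,
         n_sites = 2L, field_strengths = 3),
    list(name = "B", n_HC = 150L, n_PreHD = 150L, n_HD = 150L,
         n_sites = 2L, field_strengths = 3))
  cfg <- sim_config(cohorts = specs, n_visits = 1, seed = 67,
                    covariate_effects = zero_covariates)
  st <- generate_multi_study(cfg)
  tab <- combine_cohorts(st)
  suppressWarnings({
    am <- fit_adjustment(tab)
    adj <- apply_adjustment(am, tab)
    mix_a <- fit_all_mixtures(adj, nm, cohort = "A")
    mix_b <- fit_all_mixtures(adj, nm, cohort = "B")
  })
  b_rows <- adj[adj$cohort == "B", ]
  map_transfer <- greedy_ascent(likelihood_matrices(mix_a, b_rows),
                                n_starts = 8, seed = 1)$sequence
  map_native <- greedy_ascent(likelihood_matrices(mix_b, b_rows),
                              n_starts = 8, seed = 1)$sequence
  expect_identical(map_transfer, map_native)
})
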