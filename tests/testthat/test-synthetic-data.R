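test_that("generation is deterministic and bookkeeping is exact", {
  spec <- list(name = "X", n_HC = 10L, n_PreHD = 10L, n_HD = 10L,
               n_sites = 2L, field_strengths = 3)
  cfg <- sim_config(cohorts = list(spec), n_visits = 3, seed = 5)
  a <- generate_cohort(spec, cfg, seed = 5)
  b <- generate_cohort(spec, cfg, seed = 5)
  expect_identical(a, b)

  expect_equal(nrow(a$table), 90)
  base <- a$table[a$table$visit == 1, ]
  expect_equal(unname(table(base$group)[c("HC", "PreHD", "HD")]),
               c(10L, 10L, 10L), ignore_attr = TRUE)
  expect_false(any(duplicated(a$table[, c("subject_id", "visit")])))

  empty <- list(name = "E", n_HC = 0L, n_PreHD = 0L, n_HD = 0L,
                n_sites = 1L, field_strengths = 3)
  expect_error(generate_cohort(empty, cfg), "zero subjects")
  expect_error(sim_config(true_sequence = c(1, 1, 2, 3, 4, 5, 6, 7)),
               "permutation")
})

test_that("group labels follow the generative convention", {
  spec <- list(name = "X", n_HC = 40L, n_PreHD = 60L, n_HD = 60L,
               n_sites = 2L, field_strengths = 3)
  cfg <- sim_config(cohorts = list(spec), seed = 11)
  g <- generate_cohort(spec, cfg, seed = 11)
  tms_pos <- match("tms", g$truth$true_sequence)
  base <- g$table[g$table$visit == 1, ]
  st0 <- g$truth$true_stage[g$truth$true_stage$visit == 1, ]
  st0 <- st0$stage[match(base$subject_id, st0$subject_id)]
  expect_true(all(is.na(base$cag[base$group == "HC"])))
  expect_true(all(st0[base$group == "HC"] == 0))
  expect_true(all(st0[base$group == "HD"] >= tms_pos))
  expect_true(all(st0[base$group == "PreHD"] < tms_pos))
  expect_true(all(base$cag[base$group != "HC"] >= 36))
})

test_that("stage trajectories are monotone within subject and HC stay at 0", {
  cfg <- sim_config(cohorts = default_cohorts(scale = 0.5), seed = 3)
  for (ch in generate_multi_study(cfg)) {
    ts <- ch$truth$true_stage
    mono <- tapply(ts$stage[order(ts$subject_id, ts$visit)],
                   ts$subject_id[order(ts$subject_id, ts$visit)],
                   function(s) all(diff(s) >= 0))
    expect_true(all(mono))
    hc_ids <- ch$table$subject_id[ch$table$group == "HC"]
    expect_true(all(ts$stage[ts$subject_id %in% hc_ids] == 0))
  }
})

test_that("subjects past an event draw from the abnormal component", {
  spec <- list(name = "X", n_HC = 10L, n_PreHD = 0L, n_HD = 500L,
               n_sites = 1L, field_strengths = 3)
  cfg <- sim_config(cohorts = list(spec), n_visits = 1, seed = 21,
                    covariate_effects = zero_covariates)
  g <- generate_cohort(spec, cfg, seed = 21)
  cp <- g$truth$component_params
  ts <- g$truth$true_stage
  full <- ts$subject_id[ts$stage == nrow(cp)]   # subjects at max stage
  rows <- g$table[g$table$subject_id %in% full, ]
  expect_gt(nrow(rows), 50)
  for (j in seq_len(nrow(cp))) {
    v <- rows[[cp$marker[j]]]
    se <- cp$abnormal_sd[j] / sqrt(length(v))
    expect_lt(abs(mean(v) - cp$abnormal_mean[j]), 3 * se)
  }
})

test_that("large effect sizes give near-perfect marginal separation", {
  spec <- list(name = "X", n_HC = 0L, n_PreHD = 0L, n_HD = 500L,
               n_sites = 1L, field_strengths = 3)
  cfg <- sim_config(cohorts = list(spec), n_visits = 1, seed = 9,
                    effect_size = 5, covariate_effects = zero_covariates)
  g <- generate_cohort(spec, cfg, seed = 9)
  cp <- g$truth$component_params
  ts <- g$truth$true_stage
  pos <- match(cp$marker, g$truth$true_sequence)
  err <- vapply(seq_len(nrow(cp)), function(j) {
    v <- g$table[[cp$marker[j]]]
    abn <- ts$stage >= pos[j]
    mid <- (cp$normal_mean[j] + cp$abnormal_mean[j]) / 2
    call_abn <- if (cp$direction[j] > 0) v > mid else v < mid
    mean(call_abn != abn)
  }, numeric(1))
  expect_true(all(err < 0.05))
})

test_that("HC marginals match the configured normal component", {
  spec <- list(name = "X", n_HC = 500L, n_PreHD = 0L, n_HD = 0L,
               n_sites = 1L, field_strengths = 3)
  cfg <- sim_config(cohorts = list(spec), n_visits = 1, seed = 13,
                    covariate_effects = zero_covariates)
  g <- generate_cohort(spec, cfg, seed = 13)
  cp <- g$truth$component_params
  for (j in seq_len(nrow(cp))) {
    p <- stats::ks.test(g$table[[cp$marker[j]]], "pnorm",
                        cp$normal_mean[j], cp$normal_sd[j])$p.value
    expect_gt(p, 0.01)
  }
})

test_that("multi-study cohorts share ground truth; optional missingness works", {
  cfg <- sim_config(cohorts = default_cohorts(scale = 0.5), seed = 2)
  st <- generate_multi_study(cfg)
  expect_length(st, 3)
  seqs <- lapply(st, function(x) x$truth$true_sequence)
  expect_true(all(vapply(seqs, identical, logical(1), seqs[[1]])))
  expect_equal(length(unique(combine_cohorts(st)$subject_id)),
               sum(vapply(cfg$cohorts, function(s) s$n_HC + s$n_PreHD + s$n_HD,
                          numeric(1))))

  cfg2 <- sim_config(cohorts = default_cohorts(scale = 0.5), seed = 2,
                     missing_rate = 0.2)
  tab2 <- combine_cohorts(generate_multi_study(cfg2))
  mkcols <- default_markers()$name
  fr <- mean(is.na(as.matrix(tab2[, mkcols])))
  expect_gt(fr, 0.15); expect_lt(fr, 0.25)
})

test_that("skewed component family produces right-skewed standardized noise", {
  spec <- list(name = "X", n_HC = 800L, n_PreHD = 0L, n_HD = 0L,
               n_sites = 1L, field_strengths = 3)
  cfg <- sim_config(cohorts = list(spec), n_visits = 1, seed = 31,
                    component_family = "lognormal",
                    covariate_effects = zero_covariates)
  g <- generate_cohort(spec, cfg, seed = 31)
  cp <- g$truth$component_params
  z <- (g$table$putamen - cp$normal_mean[1]) / cp$normal_sd[1]
  expect_lt(abs(mean(z)), 0.15)
  expect_lt(abs(sd(z) - 1), 0.15)
  expect_gt(mean(z^3), 0.5)  # clear positive skew
})
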