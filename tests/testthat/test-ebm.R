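test_that("sequence likelihood matches closed forms", {
  # one subject, one marker, both densities 0.5: (1/2)(0.5 + 0.5) = 0.5
  m1 <- toy_mats(p_e = matrix(0.5), p_not_e = matrix(0.5))
  expect_equal(sequence_log_likelihood(1L, m1), log(0.5), tolerance = 1e-12)

  # K = 2, p(x|E) = 1 and p(x|not E) = 0: only the full-stage term survives
  m2 <- toy_mats(p_e = matrix(1, 1, 2), p_not_e = matrix(0, 1, 2))
  expect_equal(sequence_log_likelihood(c(1L, 2L), m2), log(1 / 3),
               tolerance = 1e-12)

  expect_error(sequence_log_likelihood(integer(0),
                                       toy_mats(matrix(1, 1, 0),
                                                matrix(1, 1, 0))),
               "K = 0")
})

test_that("sequence likelihood matches the brute-force product-sum oracle", {
  for (seed in 1:10) {
    k <- sample(2:5, 1)
    r <- random_mats(n = 5, k = k, seed = 100 + seed)
    mats <- toy_mats(r$p_e, r$p_not_e)
    s <- sample.int(k)
    expect_equal(sequence_log_likelihood(s, mats),
                 brute_force_loglik(s, r$p_e, r$p_not_e),
                 tolerance = 1e-10)
  }
  # with a missing cell (contributes factor 1 at every stage)
  r <- random_mats(n = 4, k = 3, seed = 77)
  miss <- matrix(FALSE, 4, 3); miss[2, 1] <- TRUE
  mats <- toy_mats(r$p_e, r$p_not_e, missing = miss)
  expect_equal(sequence_log_likelihood(c(2L, 3L, 1L), mats),
               brute_force_loglik(c(2L, 3L, 1L), r$p_e, r$p_not_e, miss),
               tolerance = 1e-10)
})

test_that("likelihood is invariant to subject order and consistent relabelling", {
  r <- random_mats(n = 8, k = 4, seed = 5)
  mats <- toy_mats(r$p_e, r$p_not_e)
  s <- c(3L, 1L, 4L, 2L)
  ll <- sequence_log_likelihood(s, mats)
  o <- sample(8)
  mats_o <- toy_mats(r$p_e[o, ], r$p_not_e[o, ])
  expect_equal(sequence_log_likelihood(s, mats_o), ll, tolerance = 1e-12)
  # relabel events with permutation g: columns g[j] hold old marker j
  g <- c(2L, 4L, 1L, 3L)
  pe2 <- r$p_e; pn2 <- r$p_not_e
  pe2[, g] <- r$p_e; pn2[, g] <- r$p_not_e
  mats_g <- toy_mats(pe2, pn2)
  expect_equal(sequence_log_likelihood(g[s], mats_g), ll, tolerance = 1e-12)
})

test_that("greedy ascent finds the exhaustive maximum and recovers truth", {
  m1 <- toy_mats(matrix(0.7), matrix(0.2))
  expect_identical(greedy_ascent(m1, n_starts = 1, seed = 1)$sequence, 1L)

  # strongly separated K = 4 instance vs enumeration over all 24 orders
  mats <- gaussian_mats(true_stages = rep(0:4, each = 6), s = c(2L, 4L, 1L, 3L),
                        delta = 4, seed = 8)
  gr <- greedy_ascent(mats, n_starts = 16, seed = 2)
  lls <- apply(all_perms(4), 1, sequence_log_likelihood, mats = mats)
  expect_equal(gr$log_lik, max(lls), tolerance = 1e-9)

  # K = 7, n = 300 simulated from a known sequence at effect size 2
  truth <- c(3L, 6L, 1L, 7L, 2L, 5L, 4L)
  mats7 <- gaussian_mats(true_stages = sample(rep(0:7, length.out = 300)),
                         s = truth, delta = 2, seed = 12)
  gr7 <- greedy_ascent(mats7, n_starts = 16, seed = 3)
  expect_identical(gr7$sequence, truth)
})

test_that("MCMC samples are valid permutations with a dominant true mode", {
  mats <- gaussian_mats(true_stages = rep(0:3, each = 8), s = c(3L, 1L, 2L),
                        delta = 4, seed = 21)
  post <- mcmc_sample(mats, init = c(1L, 2L, 3L), n_iter = 4000,
                      burn_in = 1000, seed = 7)
  expect_true(all(apply(post$samples, 1, function(s) setequal(s, 1:3))))
  expect_true(all(post$log_liks <= post$map_log_lik + 1e-12))
  lls <- apply(all_perms(3), 1, sequence_log_likelihood, mats = mats)
  modal <- names(sort(table(apply(post$samples, 1, paste, collapse = "")),
                      decreasing = TRUE))[1]
  brute_map <- paste(all_perms(3)[which.max(lls), ], collapse = " ")
  expect_identical(modal, gsub(" ", "", brute_map))
})

test_that("positional variance counts sample placements exactly", {
  # single sample: a permutation matrix
  p1 <- positional_variance(matrix(c(2L, 3L, 1L), 1))
  expect_equal(p1, matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3, 3),
               ignore_attr = TRUE)
  # two samples differing by one transposition
  p2 <- positional_variance(rbind(c(1L, 2L, 3L), c(2L, 1L, 3L)))
  expect_equal(unname(p2[, 1]), c(0.5, 0.5, 0))
  expect_equal(unname(p2[, 3]), c(0, 0, 1))
  # all 3! permutations once each: uniform 1/3
  p3 <- positional_variance(all_perms(3))
  expect_equal(unname(p3), matrix(1 / 3, 3, 3), tolerance = 1e-12)
  # doubly stochastic
  expect_equal(unname(rowSums(p3)), rep(1, 3), tolerance = 1e-9)
  expect_equal(unname(colSums(p3)), rep(1, 3), tolerance = 1e-9)
  expect_error(positional_variance(matrix(integer(0), 0, 3)), "no samples")
})

test_that("Kendall tau agrees with the base-R rank correlation oracle", {
  a <- letters[1:8]
  expect_equal(kendall_tau(a, a), 1)
  expect_equal(kendall_tau(a, rev(a)), -1)
  expect_equal(kendall_tau(c(0, 1, 2, 3), c(1, 0, 2, 3)), 1 - 4 / 12,
               tolerance = 1e-12)
  expect_equal(kendall_tau(c(0, 1, 2, 3), c(1, 0, 2, 3), method = "distance"),
               1 / 6, tolerance = 1e-12)
  expect_error(kendall_tau(1:3, 1:4), "length")
  expect_error(kendall_tau(1:3, c(1, 2, 5)), "different event sets")
  set.seed(71)
  for (i in 1:20) {
    k <- sample(3:9, 1)
    s1 <- sample.int(k); s2 <- sample.int(k)
    oracle <- cor(match(1:k, s1), match(1:k, s2), method = "kendall")
    expect_equal(kendall_tau(s1, s2), oracle, tolerance = 1e-12)
  }
})
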