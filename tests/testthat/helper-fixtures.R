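# Shared fixtures: hand-built likelihood objects, brute-force oracles, and
# small simulation shortcuts. Everything is generated in code at test time.

# Build an `ebm_likelihood` object directly from density matrices
# (values, not logs). Zero densities are represented faithfully (floored
# only by the -700 log clamp inside the likelihood).
toy_mats <- function(p_e, p_not_e, missing = NULL) {
  p_e <- as.matrix(p_e)
  p_not_e <- as.matrix(p_not_e)
  stopifnot(identical(dim(p_e), dim(p_not_e)))
  k <- ncol(p_e)
  mk <- colnames(p_e)
  if (is.null(mk)) mk <- paste0("m", seq_len(k))
  if (is.null(missing)) missing <- matrix(FALSE, nrow(p_e), k)
  le <- log(p_e); lne <- log(p_not_e)
  le[missing] <- 0; lne[missing] <- 0
  structure(list(log_e = le, log_not_e = lne, missing = missing,
                 meta = data.frame(row = seq_len(nrow(p_e))),
                 markers = mk, K = k),
            class = "ebm_likelihood")
}

# Independent brute-force EBM likelihood: direct product-sum evaluation,
# no log-space tricks (oracle for sequence_log_likelihood).
brute_force_loglik <- function(s, p_e, p_not_e, missing = NULL) {
  k <- length(s)
  n <- nrow(p_e)
  if (is.null(missing)) missing <- matrix(FALSE, n, k)
  total <- 0
  for (i in seq_len(n)) {
    e <- ifelse(missing[i, ], 1, p_e[i, ])
    ne <- ifelse(missing[i, ], 1, p_not_e[i, ])
    lik <- 0
    for (st in 0:k) {
      term <- 1
      for (j in seq_len(k)) {
        term <- term * if (j <= st) e[s[j]] else ne[s[j]]
      }
      lik <- lik + term
    }
    total <- total + log(lik / (k + 1))
  }
  total
}

# All permutations of 1..k (k small).
all_perms <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(k - 1)
  out <- NULL
  for (i in seq_len(k)) {
    m <- cbind(i, sub + (sub >= i))
    out <- rbind(out, m)
  }
  storage.mode(out) <- "integer"
  colnames(out) <- NULL
  out
}

# Random density matrices for likelihood tests.
random_mats <- function(n, k, seed) {
  set.seed(seed)
  list(p_e = matrix(runif(n * k, 0.02, 1), n, k),
       p_not_e = matrix(runif(n * k, 0.02, 1), n, k))
}

# Likelihood matrices simulated straight from two known Gaussian components
# (bypasses KDE fitting; for staging/sequence tests that need exact
# component densities). Subjects at given true stages under sequence s.
gaussian_mats <- function(true_stages, s, delta = 2, seed = 1) {
  set.seed(seed)
  k <- length(s)
  n <- length(true_stages)
  pos <- match(seq_len(k), s)     # event position of each marker
  x <- matrix(rnorm(n * k), n, k)
  abn <- outer(true_stages, pos, ">=")
  x <- x + delta * abn
  toy_mats(p_e = dnorm(x, mean = delta), p_not_e = dnorm(x, mean = 0))
}

# Small single-cohort reference simulation (baseline only), adjusted and
# with mixtures fitted; used by several modules.
sim_reference <- function(seed, n_each = 100, n_visits = 1, effect = 2,
                          covariate_effects = NULL) {
  spec <- list(name = "REF", n_HC = n_each, n_PreHD = n_each, n_HD = n_each,
               n_sites = 4L, field_strengths = 3)
  args <- list(cohorts = list(spec), n_visits = n_visits, seed = seed,
               effect_size = effect)
  if (!is.null(covariate_effects)) args$covariate_effects <- covariate_effects
  cfg <- do.call(sim_config, args)
  st <- generate_multi_study(cfg)
  tab <- combine_cohorts(st)
  suppressWarnings({
    am <- fit_adjustment(tab)
    adj <- apply_adjustment(am, tab)
    mix <- fit_all_mixtures(adj, default_markers()$name, cohort = "REF")
  })
  list(config = cfg, truth = st$REF$truth, raw = tab, adjusted = adj,
       mixtures = mix)
}

zero_covariates <- list(site = 0, sex = 0, tiv = 0, field_strength = 0,
                        education = 0)

`%||%` <- function(a, b) if (is.null(a)) b else a
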