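# Synthetic multi-cohort generator with known ground truth.
#
# Emulates the structure EBM assumes: a single ordered sequence of biomarker
# abnormality events shared by all gene carriers; per-subject stage driven by
# age and CAG repeat length; additive covariate and site effects on the raw
# marker values; three cohorts with different group mixes.

#' Default biomarker panel
#'
#' Five regional brain-volume markers plus three clinical scores, with
#' plausible healthy-control means/SDs (volumes in ml, clinical scores in
#' native units) and the pathological direction of abnormality: atrophy
#' (-1) for subcortical/white-matter volumes, enlargement (+1) for the
#' lateral ventricles, increase (+1) for the motor score, decline (-1) for
#' the cognitive scores.
#'
#' @return A data.frame with columns `name`, `type` ("imaging"/"clinical"),
#'   `normal_mean`, `normal_sd`, `direction`.
#' @export
default_markers <- function() {
  data.frame(
    name = c("putamen", "caudate", "pallidum", "white_matter",
             "lateral_ventricles", "tms", "sdmt", "swrt"),
    type = c(rep("imaging", 5), rep("clinical", 3)),
    normal_mean = c(10.5, 7.8, 3.9, 470, 28, 2.0, 52, 95),
    normal_sd   = c(1.0, 0.9, 0.5, 45, 12, 2.0, 10, 16),
    direction   = c(-1, -1, -1, -1, +1, +1, -1, -1),
    stringsAsFactors = FALSE
  )
}

#' Default three-cohort design
#'
#' A TRACK-like balanced multi-site cohort, a PREDICT-like PreHD-heavy cohort
#' with very few manifest HD participants, and an IMAGE-like small
#' single-site cohort.
#'
#' @param scale multiply all group counts by this factor (rounded, min 1 for
#'   nonzero groups); handy for quick runs.
#' @return List of cohort specs, each a list with `name`, `n_HC`, `n_PreHD`,
#'   `n_HD`, `n_sites`, `field_strengths`.
#' @export
default_cohorts <- function(scale = 1) {
  sc <- function(n) if (n == 0) 0L else max(1L, as.integer(round(n * scale)))
  list(
    list(name = "TRACK",   n_HC = sc(100), n_PreHD = sc(104), n_HD = sc(80),
         n_sites = 4L,  field_strengths = 3),
    list(name = "PREDICT", n_HC = sc(36),  n_PreHD = sc(132), n_HD = sc(3),
         n_sites = 20L, field_strengths = c(1.5, 3)),
    list(name = "IMAGE",   n_HC = sc(22),  n_PreHD = sc(28),  n_HD = sc(27),
         n_sites = 1L,  field_strengths = 3)
  )
}

#' Simulation configuration
#'
#' Bundles every knob of the generator. The defaults define the reference
#' study conditions used throughout the package's validation: 8 biomarkers
#' whose true event order places the four atrophy markers first, the motor
#' score fifth and the lateral ventricles last; CAG-dependent onset age
#' `age0 = a0 - a1 * (CAG - 35.5)` and progression rate
#' `r * (CAG - 35.5)` events/year; and modest additive covariate effects.
#'
#' @param markers biomarker panel, see [default_markers()].
#' @param true_sequence integer permutation of `seq_len(nrow(markers))`
#'   giving the ground-truth event order (indices into `markers`).
#' @param cohorts list of cohort specs, see [default_cohorts()].
#' @param n_visits visits per subject (first is baseline).
#' @param visit_interval_years spacing between visits, years.
#' @param cag_range inclusive integer range of carrier CAG repeat lengths.
#' @param onset numeric `c(a0, a1)`: age at first event is
#'   `a0 - a1 * (CAG - 35.5)`.
#' @param rate events per year per unit of `(CAG - 35.5)`.
#' @param effect_size separation between normal and abnormal component means,
#'   in control-SD units.
#' @param covariate_effects named list of additive effect magnitudes in
#'   control-SD units: `site` (SD of random site offsets), `sex`, `tiv`,
#'   `field_strength` (imaging markers), `education` (clinical markers).
#'   Set all to 0 for covariate-free data.
#' @param component_family `"gaussian"` or `"lognormal"` (right-skewed
#'   shifted-lognormal components, exercising the non-Gaussian case that
#'   motivates KDE mixtures).
#' @param missing_rate per-cell probability that a marker value is missing.
#' @param seed integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(markers = default_markers(),
                       true_sequence = c(1, 2, 3, 4, 6, 7, 8, 5),
                       cohorts = default_cohorts(),
                       n_visits = 3,
                       visit_interval_years = 1,
                       cag_range = c(40, 49),
                       onset = c(a0 = 70, a1 = 4),
                       rate = 0.05,
                       effect_size = 2.0,
                       covariate_effects = list(site = 0.3, sex = 0.2,
                                                tiv = 0.5,
                                                field_strength = 0.3,
                                                education = 0.2),
                       component_family = c("gaussian", "lognormal"),
                       missing_rate = 0,
                       seed = 1L) {
  component_family <- match.arg(component_family)
  k <- nrow(markers)
  if (length(true_sequence) != k || !setequal(true_sequence, seq_len(k)))
    stop("`true_sequence` must be a permutation of 1..", k)
  if (n_visits < 1 || visit_interval_years <= 0)
    stop("need n_visits >= 1 and positive visit interval")
  if (effect_size <= 0) stop("effect_size must be > 0")
  if (rate <= 0) stop("rate must be > 0")
  cfg <- list(markers = markers, true_sequence = as.integer(true_sequence),
              cohorts = cohorts, n_visits = as.integer(n_visits),
              visit_interval_years = visit_interval_years,
              cag_range = as.integer(cag_range),
              onset = c(a0 = unname(onset[1]), a1 = unname(onset[2])),
              rate = rate, effect_size = effect_size,
              covariate_effects = covariate_effects,
              component_family = component_family,
              missing_rate = missing_rate, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Per-marker component parameters implied by a config: abnormal mean is
# shifted effect_size SDs in the pathological direction; equal SDs.
component_params <- function(config) {
  m <- config$markers
  data.frame(
    marker = m$name,
    normal_mean = m$normal_mean, normal_sd = m$normal_sd,
    abnormal_mean = m$normal_mean + m$direction * config$effect_size * m$normal_sd,
    abnormal_sd = m$normal_sd,
    direction = m$direction,
    stringsAsFactors = FALSE
  )
}

# Draw standardized (mean 0, sd 1) noise, optionally right-skewed.
draw_noise <- function(n, family) {
  if (family == "gaussian") return(rnorm(n))
  sdl <- 0.5
  z <- rlnorm(n, meanlog = 0, sdlog = sdl)
  mu <- exp(sdl^2 / 2)
  (z - mu) / sqrt((exp(sdl^2) - 1) * exp(sdl^2))
}

#' Generate one synthetic cohort
#'
#' Draws subjects per the cohort spec, assigns carriers a CAG repeat length
#' and a baseline stage consistent with their clinical group, computes the
#' deterministic stage trajectory `clip(round(r * (CAG - 35.5) *
#' (age - age0)), 0, K)` across visits, and draws each marker from its normal
#' or abnormal component according to whether its event position has been
#' passed. Covariate effects (site offset, sex, TIV and field strength for
#' imaging markers, education for clinical markers) are added afterwards.
#' Group labels follow the generative convention: HC iff non-carrier, HD iff
#' baseline stage >= the motor-score event position, else PreHD.
#'
#' @param spec a single cohort spec (see [default_cohorts()]).
#' @param config a [sim_config()].
#' @param seed integer seed for this cohort.
#' @return List with `table` (one row per subject-visit) and `truth`
#'   (`true_sequence` as marker names, `true_stage`, `true_onset_age`,
#'   `component_params`).
#' @export
generate_cohort <- function(spec, config, seed = config$seed) {
  n_sub <- spec$n_HC + spec$n_PreHD + spec$n_HD
  if (n_sub == 0) stop("cohort '", spec$name, "': zero subjects requested in all groups")
  k <- nrow(config$markers)
  if (!setequal(config$true_sequence, seq_len(k)))
    stop("invalid true_sequence in config")
  set.seed(seed)

  mk <- config$markers
  cp <- component_params(config)
  # position of each marker in the event sequence (1..K)
  pos <- match(seq_len(k), config$true_sequence)
  tms_pos <- pos[match("tms", mk$name)]
  if (is.na(tms_pos)) tms_pos <- ceiling(k / 2)  # panel without a motor score

  group <- rep(c("HC", "PreHD", "HD"), c(spec$n_HC, spec$n_PreHD, spec$n_HD))
  carrier <- group != "HC"
  sex <- rbinom(n_sub, 1, 0.5)
  tiv <- rnorm(n_sub, 2.2 - 0.15 * sex, 0.18)
  education <- sample(1:5, n_sub, replace = TRUE)
  site_levels <- paste0(spec$name, "_site", seq_len(spec$n_sites))
  site <- sample(site_levels, n_sub, replace = TRUE)
  site_fs <- rep_len(spec$field_strengths, spec$n_sites)
  if (spec$n_sites > 1) site_fs <- sample(site_fs)
  fs <- site_fs[match(site, site_levels)]

  # carriers: CAG weighted toward the low end of the range (population-like)
  cags <- config$cag_range[1]:config$cag_range[2]
  cag <- rep(NA_integer_, n_sub)
  cag[carrier] <- sample(cags, sum(carrier), replace = TRUE,
                         prob = exp(-0.35 * (cags - min(cags))))
  burden_u <- cag - 35.5
  age0 <- config$onset["a0"] - config$onset["a1"] * burden_u

  # baseline target stage by group; early-manifest recruitment for HD
  k0 <- integer(n_sub)
  pre <- group == "PreHD"; hd <- group == "HD"
  if (any(pre)) k0[pre] <- sample(0:(tms_pos - 1), sum(pre), replace = TRUE)
  if (any(hd)) {
    hs <- tms_pos:k
    k0[hd] <- sample(hs, sum(hd), replace = TRUE,
                     prob = c(0.35, 0.3, 0.2, 0.15)[seq_along(hs)])
  }
  # baseline age that rounds to the target stage
  u <- k0 + runif(n_sub, -0.45, 0.45)
  u[carrier & k0 == 0] <- runif(sum(carrier & k0 == 0), -3, 0.45)
  age_base <- numeric(n_sub)
  age_base[carrier] <- age0[carrier] +
    u[carrier] / (config$rate * burden_u[carrier])
  age_base[!carrier] <- pmin(pmax(rnorm(sum(!carrier), 45, 10), 25), 70)

  subject_id <- sprintf("%s_%04d", spec$name, seq_len(n_sub))

  nv <- config$n_visits
  idx <- rep(seq_len(n_sub), each = nv)
  visit <- rep(seq_len(nv), times = n_sub)
  age <- age_base[idx] + (visit - 1) * config$visit_interval_years
  stage <- integer(length(idx))
  ci <- carrier[idx]
  stage[ci] <- pmin(pmax(round(config$rate * burden_u[idx][ci] *
                                 (age[ci] - age0[idx][ci])), 0), k)

  # site-by-marker random offsets, in control-SD units
  ce <- config$covariate_effects
  site_off <- matrix(rnorm(spec$n_sites * k, 0, ce$site %||% 0),
                     nrow = spec$n_sites, dimnames = list(site_levels, mk$name))

  values <- matrix(NA_real_, nrow = length(idx), ncol = k,
                   dimnames = list(NULL, mk$name))
  fs_z <- (fs - 2.25) / 0.75
  tiv_z <- (tiv - 2.15) / 0.2
  edu_z <- (education - 3) / 1.4
  sex_c <- sex - 0.5
  for (j in seq_len(k)) {
    abn <- stage >= pos[j]
    mean_j <- ifelse(abn, cp$abnormal_mean[j], cp$normal_mean[j])
    v <- mean_j + mk$normal_sd[j] * draw_noise(length(idx), config$component_family)
    cov_eff <- site_off[match(site[idx], site_levels), j] +
      (ce$sex %||% 0) * sex_c[idx]
    if (mk$type[j] == "imaging") {
      cov_eff <- cov_eff + (ce$tiv %||% 0) * tiv_z[idx] +
        (ce$field_strength %||% 0) * fs_z[idx]
    } else {
      cov_eff <- cov_eff + (ce$education %||% 0) * edu_z[idx]
    }
    values[, j] <- v + mk$normal_sd[j] * cov_eff
  }
  if (config$missing_rate > 0) {
    values[runif(length(values)) < config$missing_rate] <- NA_real_
  }

  table <- data.frame(
    subject_id = subject_id[idx], cohort = spec$name, visit = visit,
    group = group[idx], age = age, sex = sex[idx], site = site[idx],
    field_strength = fs[idx], tiv = tiv[idx], education = education[idx],
    cag = cag[idx], stringsAsFactors = FALSE
  )
  table <- cbind(table, as.data.frame(values))

  truth <- list(
    true_sequence = mk$name[config$true_sequence],
    true_stage = data.frame(subject_id = subject_id[idx], visit = visit,
                            stage = stage, stringsAsFactors = FALSE),
    true_onset_age = setNames(ifelse(carrier, age0, NA_real_), subject_id),
    component_params = cp
  )
  list(table = table, truth = truth)
}

#' Generate all cohorts of a multi-study design
#'
#' All cohorts share the ground-truth event sequence and component
#' parameters but differ in group mix, sites and covariate draws.
#'
#' @param config a [sim_config()] with at least one cohort spec.
#' @return Named list (by cohort name) of [generate_cohort()] results.
#' @export
generate_multi_study <- function(config) {
  if (length(config$cohorts) < 1) stop("need at least one cohort spec")
  out <- lapply(seq_along(config$cohorts), function(i) {
    generate_cohort(config$cohorts[[i]], config,
                    seed = fan_seed(config$seed, i))
  })
  names(out) <- vapply(config$cohorts, `[[`, character(1), "name")
  out
}

#' Combine cohort tables into one long table
#' @param studies result of [generate_multi_study()].
#' @return Single data.frame with all subject-visit rows.
#' @export
combine_cohorts <- function(studies) {
  do.call(rbind, c(lapply(studies, `[[`, "table"), make.row.names = FALSE))
}

#' Write a biomarker table as CSV / ground truth as JSON
#' @param table biomarker table.
#' @param path output file.
#' @export
write_biomarker_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_biomarker_table
#' @param truth truth list from [generate_cohort()].
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}
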