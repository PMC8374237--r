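# Full-analysis orchestration: simulate/read -> adjust -> fit mixtures on
# the reference cohort -> infer sequences per cohort -> stage -> compare ->
# regress. A single global seed fans out to per-stage substreams so stages
# are individually reproducible.

#' Pipeline configuration
#'
#' @param sim a [sim_config()] to simulate from, or NULL when reading CSVs.
#' @param cohort_paths named character vector of CSV paths (used when `sim`
#'   is NULL).
#' @param reference reference cohort name for mixture fitting and for the
#'   common staging scale used by the progression models.
#' @param markers marker column names.
#' @param orientation named orientation vector.
#' @param greedy_starts random restarts for the MAP search.
#' @param mcmc list with `n_iter`, `burn_in` (set `n_iter = 0` to skip MCMC
#'   and use the greedy result alone).
#' @param stage_target target stage for age-at-stage prediction (default 5,
#'   the motor-score event position in the default panel).
#' @param min_cag_subjects minimum subjects per CAG group in the
#'   progression models.
#' @param out_dir output directory (NULL: nothing written).
#' @param seed global integer seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), cohort_paths = NULL,
                       reference = "TRACK",
                       markers = default_markers()$name,
                       orientation = marker_orientations(markers),
                       greedy_starts = 16,
                       mcmc = list(n_iter = 20000, burn_in = 10000),
                       stage_target = 5,
                       min_cag_subjects = 3,
                       out_dir = NULL, seed = 1L) {
  if (is.null(sim) && is.null(cohort_paths))
    stop("provide either a sim config or cohort CSV paths")
  if (length(markers) == 0) stop("biomarker list is empty")
  structure(list(sim = sim, cohort_paths = cohort_paths,
                 reference = reference, markers = markers,
                 orientation = orientation, greedy_starts = greedy_starts,
                 mcmc = mcmc, stage_target = stage_target,
                 min_cag_subjects = min_cag_subjects,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full multi-cohort analysis
#'
#' Mixture fits use the reference cohort's baseline rows only; sequence
#' inference per cohort uses that cohort's baseline rows; staging covers all
#' visits (per-cohort MAP sequence for the cohort-level staging output, the
#' reference sequence for the pooled progression models, so all cohorts
#' share one stage scale); pairwise Kendall tau is computed for all cohort
#' pairs. When `out_dir` is set, all artifacts are written together with a
#' manifest recording config, seed, package version and file checksums.
#'
#' @param config a [run_config()].
#' @return List: `tables` (raw and adjusted), `truth` (when simulated),
#'   `adjustment`, `mixtures`, `sequences` (per cohort: greedy result, MAP,
#'   optional `ebm_posterior`, positional variance), `tau` (pairwise
#'   matrix), `staged` (per-cohort-sequence), `staged_ref` (reference
#'   sequence, all cohorts), `progression` (per-CAG fits), `age_at_target`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!is.null(config$reference)) ref <- config$reference
  markers <- config$markers

  # 1. data
  truth <- NULL
  if (!is.null(config$sim)) {
    sim <- config$sim
    sim$seed <- config$seed
    studies <- generate_multi_study(sim)
    raw <- combine_cohorts(studies)
    truth <- lapply(studies, `[[`, "truth")
  } else {
    raw <- do.call(rbind, c(lapply(config$cohort_paths, read_biomarker_table,
                                   markers = markers),
                            make.row.names = FALSE))
  }
  if (!ref %in% raw$cohort)
    stop("reference cohort '", ref, "' not among inputs")

  # 2. covariate adjustment
  adj_model <- fit_adjustment(raw, markers = markers,
                              orientation = config$orientation)
  adjusted <- apply_adjustment(adj_model, raw)

  # 3. mixtures on reference baseline
  mixtures <- fit_all_mixtures(adjusted, markers, cohort = ref)

  # 4. sequences per cohort (baseline rows)
  cohorts <- unique(adjusted$cohort)
  sequences <- list()
  for (i in seq_along(cohorts)) {
    ch <- cohorts[i]
    base <- adjusted[adjusted$cohort == ch & adjusted$visit == 1, , drop = FALSE]
    mats <- likelihood_matrices(mixtures, base, markers)
    gr <- greedy_ascent(mats, n_starts = config$greedy_starts,
                        seed = fan_seed(config$seed, 10 + i))
    post <- NULL
    map <- gr$sequence
    map_ll <- gr$log_lik
    if ((config$mcmc$n_iter %||% 0) > 0) {
      post <- mcmc_sample(mats, init = gr$sequence,
                          n_iter = config$mcmc$n_iter,
                          burn_in = config$mcmc$burn_in,
                          seed = fan_seed(config$seed, 20 + i))
      if (post$map_log_lik > map_ll) { map <- post$map; map_ll <- post$map_log_lik }
      post$map <- map; post$map_log_lik <- map_ll
    }
    sequences[[ch]] <- list(
      greedy = gr, map = map, map_log_lik = map_ll, posterior = post,
      map_markers = markers[map],
      positional_variance = if (!is.null(post)) positional_variance(post))
  }

  # 5. pairwise sequence similarity
  tau <- matrix(NA_real_, length(cohorts), length(cohorts),
                dimnames = list(cohorts, cohorts))
  for (a in cohorts) for (b in cohorts) {
    tau[a, b] <- kendall_tau(sequences[[a]]$map, sequences[[b]]$map)
  }

  # 6. staging (all visits)
  staged <- do.call(rbind, c(lapply(cohorts, function(ch) {
    stage_table(mixtures, adjusted[adjusted$cohort == ch, , drop = FALSE],
                sequences[[ch]]$map, markers)
  }), make.row.names = FALSE))
  staged_ref <- stage_table(mixtures, adjusted, sequences[[ref]]$map, markers)

  # 7. progression vs age per CAG group, on the common reference scale
  progression <- withCallingHandlers(
    fit_progression_by_cag(staged_ref, min_subjects = config$min_cag_subjects),
    warning = function(w) invokeRestart("muffleWarning"))
  age_at_target <- lapply(progression, age_at_stage,
                          target_stage = config$stage_target,
                          seed = fan_seed(config$seed, 30))

  res <- list(tables = list(raw = raw, adjusted = adjusted), truth = truth,
              adjustment = adj_model, mixtures = mixtures,
              sequences = sequences, tau = tau,
              staged = staged, staged_ref = staged_ref,
              progression = progression, age_at_target = age_at_target,
              config = config)
  if (!is.null(config$out_dir)) res$manifest <- write_results(res, config$out_dir)
  res
}

# Write all artifacts plus a manifest of md5 checksums.
write_results <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(...) file.path(out_dir, ...)
  write_biomarker_table(res$tables$adjusted, f("adjusted_table.csv"))
  write_mixtures(res$mixtures, f("mixtures.json"))
  for (ch in names(res$sequences)) {
    sq <- res$sequences[[ch]]
    if (!is.null(sq$posterior))
      write_posterior(sq$posterior,
                      json_path = f(paste0("sequence_", ch, ".json")),
                      csv_path = f(paste0("positional_variance_", ch, ".csv")))
  }
  jsonlite::write_json(
    lapply(res$sequences, function(sq)
      list(map = sq$map, map_markers = sq$map_markers,
           map_log_lik = sq$map_log_lik)),
    f("map_sequences.json"), auto_unbox = TRUE, digits = NA)
  write.csv(data.frame(cohort = rownames(res$tau), res$tau,
                       check.names = FALSE), f("kendall_tau.csv"),
            row.names = FALSE)
  write.csv(res$staged, f("stages.csv"), row.names = FALSE)
  write.csv(res$staged_ref, f("stages_reference_sequence.csv"),
            row.names = FALSE)
  prog <- lapply(res$progression, function(p)
    list(cag = p$cag_group, degree = p$degree, beta = p$beta,
         tau2 = p$tau2, sigma2 = p$sigma2, n_subjects = p$n_subjects,
         mean_band_width = p$mean_band_width))
  jsonlite::write_json(list(fits = prog, age_at_target = res$age_at_target),
                       f("progression.json"), auto_unbox = TRUE, digits = NA)

  files <- sort(list.files(out_dir, full.names = TRUE))
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    seed = res$config$seed,
    reference = res$config$reference,
    markers = res$config$markers,
    package_version = as.character(utils::packageVersion("hdebm")),
    files = as.list(setNames(unname(tools::md5sum(files)), basename(files))))
  jsonlite::write_json(manifest, f("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  manifest
}
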