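# Control-referenced covariate adjustment and derived scores.
#
# Markers are regressed against covariates using baseline healthy-control
# rows only, within each cohort separately; all rows are then residualized
# with the control-fitted coefficients, z-scaled by the control residual SD,
# and multiplied by a fixed orientation sign so that larger always means
# more abnormal.

#' Default a-priori orientation signs
#'
#' +1 where abnormality increases the raw value (lateral ventricles, motor
#' score), -1 where abnormality decreases it (atrophying volumes, cognitive
#' scores). Fixed from pathology rather than learned, which removes a
#' component-labelling ambiguity in the mixture fits; override per marker if
#' a panel differs.
#'
#' @param markers character vector of marker names.
#' @return Named numeric vector of +1/-1.
#' @export
marker_orientations <- function(markers = default_markers()$name) {
  plus <- c("lateral_ventricles", "tms")
  setNames(ifelse(markers %in% plus, 1, -1), markers)
}

#' Default covariate sets
#'
#' Imaging markers: age, sex, site, TIV and scanner field strength (the
#' latter only matters in cohorts acquiring at more than one strength);
#' clinical markers: age, sex, site and education.
#' @return List with elements `imaging` and `clinical`.
#' @export
default_covariate_sets <- function() {
  list(imaging = c("age", "sex", "tiv", "field_strength", "site"),
       clinical = c("age", "sex", "education", "site"))
}

# Build a design matrix for one cohort's rows. `site` is dummy-coded against
# a stored reference level; unseen levels map to the reference with warning.
build_design <- function(df, covars, site_levels = NULL) {
  cols <- list(`(Intercept)` = rep(1, nrow(df)))
  for (cv in covars) {
    if (cv == "site") {
      lv <- site_levels %||% unique(df$site)
      s <- df$site
      unseen <- !(s %in% lv)
      if (any(unseen)) {
        warning("unseen site level(s) ", paste(unique(s[unseen]), collapse = ", "),
                " mapped to reference level ", lv[1])
        s[unseen] <- lv[1]
      }
      if (length(lv) > 1) {
        for (l in lv[-1]) cols[[paste0("site", l)]] <- as.numeric(s == l)
      }
    } else {
      cols[[cv]] <- as.numeric(df[[cv]])
    }
  }
  x <- do.call(cbind, cols)
  colnames(x) <- names(cols)
  x
}

#' Fit the control-referenced adjustment model
#'
#' Ordinary least squares of each marker on its covariate set, using
#' baseline healthy-control rows only, separately within each cohort.
#' Covariates that are constant among a cohort's controls (e.g. site in a
#' single-site cohort, field strength at one magnet) are dropped with a
#' warning; coefficients aliased by residual collinearity are set to zero
#' with a warning.
#'
#' @param table biomarker table (long format, see [generate_cohort()]).
#' @param markers character vector of marker column names.
#' @param covariate_sets list as from [default_covariate_sets()].
#' @param orientation named +1/-1 vector, see [marker_orientations()].
#' @param marker_types named character vector mapping marker to
#'   "imaging"/"clinical"; defaults to the [default_markers()] panel.
#' @param baseline_visit which visit index counts as baseline.
#' @param min_controls minimum HC rows required per cohort.
#' @return An object of class `adjustment_model`: per cohort, per marker,
#'   the coefficient vector, site reference levels, control residual SD and
#'   orientation sign.
#' @export
fit_adjustment <- function(table,
                           markers = intersect(default_markers()$name, names(table)),
                           covariate_sets = default_covariate_sets(),
                           orientation = marker_orientations(markers),
                           marker_types = NULL,
                           baseline_visit = 1,
                           min_controls = 10) {
  if (is.null(marker_types)) {
    dm <- default_markers()
    marker_types <- setNames(dm$type, dm$name)[markers]
    marker_types[is.na(marker_types)] <- "imaging"
    names(marker_types) <- markers
  }
  if (!all(markers %in% names(orientation)))
    stop("orientation must cover every marker")
  cohorts <- unique(table$cohort)
  fits <- lapply(cohorts, function(ch) {
    hc <- table[table$cohort == ch & table$group == "HC" &
                  table$visit == baseline_visit, , drop = FALSE]
    if (nrow(hc) < min_controls)
      stop("cohort '", ch, "': only ", nrow(hc), " baseline HC rows (need >= ",
           min_controls, ")")
    site_levels <- sort(unique(hc$site))  # first level = reference
    per_marker <- lapply(markers, function(mkr) {
      covars <- covariate_sets[[marker_types[[mkr]]]]
      # drop covariates constant among this cohort's controls
      const <- vapply(setdiff(covars, "site"), function(cv) {
        length(unique(hc[[cv]])) < 2
      }, logical(1))
      if (any(const)) {
        warning("cohort '", ch, "', marker '", mkr, "': dropping constant covariate(s) ",
                paste(names(const)[const], collapse = ", "))
        covars <- setdiff(covars, names(const)[const])
      }
      y <- hc[[mkr]]
      ok <- is.finite(y)
      x <- build_design(hc[ok, , drop = FALSE], covars, site_levels)
      fit <- lm.fit(x, y[ok])
      beta <- fit$coefficients
      if (anyNA(beta)) {
        warning("cohort '", ch, "', marker '", mkr,
                "': singular design; aliased coefficient(s) set to zero: ",
                paste(names(beta)[is.na(beta)], collapse = ", "))
        beta[is.na(beta)] <- 0
      }
      res <- fit$residuals
      list(coef = beta, covars = covars, site_levels = site_levels,
           resid_mean = mean(res), resid_sd = sd(res),
           orientation = unname(orientation[mkr]))
    })
    names(per_marker) <- markers
    per_marker
  })
  names(fits) <- cohorts
  structure(list(fits = fits, markers = markers,
                 marker_types = marker_types,
                 baseline_visit = baseline_visit),
            class = "adjustment_model")
}

#' Apply a fitted adjustment
#'
#' Residualizes every row (controls and gene carriers alike) with the
#' control-fitted coefficients of its own cohort, z-scales by the control
#' residual SD, and applies the orientation sign so larger = more abnormal
#' for every marker.
#'
#' @param model an `adjustment_model`.
#' @param table biomarker table covering the model's markers.
#' @return The table with marker columns replaced by adjusted, oriented
#'   z-scores.
#' @export
apply_adjustment <- function(model, table) {
  out <- table
  for (ch in unique(table$cohort)) {
    if (!ch %in% names(model$fits))
      stop("no adjustment fitted for cohort '", ch, "'")
    rows <- which(table$cohort == ch)
    sub <- table[rows, , drop = FALSE]
    for (mkr in model$markers) {
      pm <- model$fits[[ch]][[mkr]]
      x <- build_design(sub, pm$covars, pm$site_levels)
      pred <- drop(x %*% pm$coef[colnames(x)])
      out[rows, mkr] <- pm$orientation * (sub[[mkr]] - pred) / pm$resid_sd
    }
  }
  out
}

#' Disease burden score
#'
#' Lifetime genetic-exposure proxy `age * (CAG - 35.5)`.
#'
#' @param age age in years (>= 0).
#' @param cag CAG repeat length; values at or below 35.5 are non-pathogenic
#'   and trigger a warning (the value is still returned).
#' @return Numeric burden score.
#' @examples
#' disease_burden(50, 40)  # 225
#' @export
disease_burden <- function(age, cag) {
  stopifnot(all(age >= 0, na.rm = TRUE))
  if (any(cag <= 35.5, na.rm = TRUE))
    warning("cag <= 35.5: non-carrier range, burden score is not meaningful")
  age * (cag - 35.5)
}
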