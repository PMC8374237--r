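# Reading and validating biomarker tables; artifact writers.

required_meta_cols <- c("subject_id", "cohort", "visit", "group", "age",
                        "sex", "site", "field_strength", "tiv", "education",
                        "cag")

#' Read and validate a biomarker table
#'
#' CSV dialect written by [write_biomarker_table()]: one header row, the
#' metadata columns, then one column per marker. Rows with non-numeric
#' marker cells are rejected with a location report; unknown extra columns
#' are preserved with a warning.
#'
#' @param path CSV file.
#' @param markers expected marker column names.
#' @return Validated data.frame.
#' @export
read_biomarker_table <- function(path, markers = default_markers()$name) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c(required_meta_cols, markers), names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  extra <- setdiff(names(df), c(required_meta_cols, markers))
  if (length(extra))
    warning("unknown column(s) preserved: ", paste(extra, collapse = ", "))
  bad_rows <- integer(0)
  for (m in markers) {
    if (!is.numeric(df[[m]])) {
      suppress <- suppressWarnings(as.numeric(df[[m]]))
      bad <- which(!is.na(df[[m]]) & df[[m]] != "" & is.na(suppress))
      if (length(bad)) {
        warning("non-numeric value(s) in marker '", m, "' at data row(s) ",
                paste(head(bad, 10), collapse = ", "), "; row(s) rejected")
        bad_rows <- union(bad_rows, bad)
      }
      df[[m]] <- suppress
    }
  }
  if (length(bad_rows)) df <- df[-bad_rows, , drop = FALSE]
  dup <- duplicated(df[, c("cohort", "subject_id", "visit")])
  if (any(dup))
    stop("duplicate (subject_id, visit) pair(s) within a cohort at row(s) ",
         paste(head(which(dup), 10), collapse = ", "))
  df
}

#' Write a sequence posterior (JSON) and its positional variance (CSV)
#'
#' The positional-variance CSV lists events ordered by their MAP position,
#' matching the usual positional-variance-diagram layout.
#'
#' @param post an `ebm_posterior`.
#' @param json_path,csv_path output paths (either may be NULL to skip).
#' @export
write_posterior <- function(post, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path)) {
    obj <- list(map = post$map, map_log_lik = post$map_log_lik,
                accept_rate = post$accept_rate, settings = post$settings,
                markers = post$markers,
                samples = apply(post$samples, 1, paste, collapse = " "))
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    p <- positional_variance(post)
    p <- p[post$map, , drop = FALSE]
    write.csv(data.frame(event = rownames(p), p, check.names = FALSE),
              csv_path, row.names = FALSE)
  }
  invisible(post)
}
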