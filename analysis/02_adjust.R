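#!/usr/bin/env Rscript
# Step 2: control-referenced covariate adjustment. Each marker is regressed
# on its covariate set using baseline healthy controls of each cohort, all
# rows are residualized and z-scaled, and orientation signs make larger =
# more abnormal everywhere.

library(hdebm)

out <- "results/analysis"
paths <- Sys.glob(file.path(out, "cohort_*.csv"))
stopifnot(length(paths) > 0)
tab <- do.call(rbind, c(lapply(paths, read_biomarker_table),
                        make.row.names = FALSE))

model <- suppressWarnings(fit_adjustment(tab))
# carrier-only sites are mapped to the reference level by design; quiet here
adj <- suppressWarnings(apply_adjustment(model, tab))
write_biomarker_table(adj, file.path(out, "adjusted.csv"))

cat("Adjusted", nrow(adj), "rows;",
    "control residual SDs used for z-scaling:\n")
for (ch in names(model$fits)) {
  sds <- vapply(model$fits[[ch]], `[[`, numeric(1), "resid_sd")
  cat(sprintf("  %-8s %s\n", ch,
              paste(sprintf("%s=%.3g", names(sds), sds), collapse = " ")))
}
cat("Post-adjustment baseline group means (oriented z-scores, putamen):\n")
base <- adj[adj$visit == 1, ]
print(round(tapply(base$putamen, base$group, mean), 2))
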