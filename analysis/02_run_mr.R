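#!/usr/bin/env Rscript
# Run the full two-sample MR pipeline on the synthetic cohorts written by
# 01_simulate_cohorts.R: instrument selection (significance, LD clumping,
# F screen, outcome-overlap exclusion), harmonization, the estimator suite
# (random-effects IVW primary; weighted median, MR-Egger, radial outlier
# removal, leave-one-out as sensitivity), and the Bonferroni-tiered forest
# table. Writes report tables and harmonized instruments under results/.

library(mrkit)

data_dir <- file.path("results", "data")
out_dir <- "results"
if (!dir.exists(data_dir)) stop("run analysis/01_simulate_cohorts.R first")

labels <- c("monocyte_like", "lymphocyte_like", "neutrophil_like")
exposures <- list()
ld_list <- list()
outcome <- NULL
for (label in labels) {
  exposures[[label]] <- read_sumstats(
    file.path(data_dir, paste0(label, "_exposure.tsv")), trait_label = label)
  ld_list[[label]] <- read_ld_matrix(
    file.path(data_dir, paste0(label, "_ld_info.tsv")),
    file.path(data_dir, paste0(label, "_ld_matrix.tsv")))
  if (is.null(outcome)) {
    outcome <- read_sumstats(
      file.path(data_dir, paste0(label, "_outcome.tsv")),
      trait_label = "t2d_like", trait_type = "binary")
  }
}
# Each exposure has its own matched outcome table in this synthetic design;
# the pipeline also supports a single shared outcome GWAS, which is the
# consortium situation. Run each pair separately for clean truth recovery.
all_rows <- list()
for (label in labels) {
  outcome_l <- read_sumstats(
    file.path(data_dir, paste0(label, "_outcome.tsv")),
    trait_label = "t2d_like", trait_type = "binary")
  run <- run_mr(exposures[label], outcome_l, ld_list[label],
                selection = selection_config(p_threshold = 5e-8),
                outcome_label = "t2d_like", n_boot = 1000, seed = 20260923,
                bonferroni_m = length(labels))
  all_rows[[label]] <- run$rows
  write_harmonized(run$harmonized[[label]],
                   file.path(out_dir, paste0(label, "_harmonized.tsv")))
  if (!is.null(run$loo[[label]])) {
    write.table(run$loo[[label]],
                file.path(out_dir, paste0(label, "_leave_one_out.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
}
rows <- do.call(rbind, c(all_rows, list(make.row.names = FALSE)))
write_report(rows, file.path(out_dir, "mr_report.tsv"))
forest <- render_forest_table(rows)
writeLines(forest, file.path(out_dir, "forest_table.txt"))
writeLines(forest)
cat("\nTrue effects: monocyte_like OR", round(exp(0.06), 3),
    "| lymphocyte_like OR 1.000 | neutrophil_like OR",
    round(exp(0.03), 3), "\n")
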