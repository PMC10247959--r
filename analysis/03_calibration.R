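#!/usr/bin/env Rscript
# Monte-Carlo calibration of the estimator suite under the simulator's
# standard two-sample conditions: type-I error at the null, causal-effect
# recovery and CI coverage, behavior under balanced pleiotropy (RE vs FE
# coverage), and Egger intercept recovery under directional pleiotropy.
# Writes results/calibration.tsv. Replicate counts are chosen to keep the
# whole script a few minutes on one CPU; the package's tests run the same
# studies at 1000 replicates.

library(mrkit)

dir.create("results", showWarnings = FALSE)
n_reps <- 500

studies <- list(
  null = list(
    cfg = sim_config(n_snp = 50, beta_causal = 0, seed = 2201),
    methods = c("ivw_re", "weighted_median"),
    selection = selection_config(p_threshold = 5e-8)),
  causal_0.1 = list(
    cfg = sim_config(n_snp = 50, beta_causal = 0.1, seed = 2202),
    methods = c("ivw_re", "weighted_median", "egger"),
    selection = selection_config(p_threshold = 5e-8)),
  balanced_pleiotropy = list(
    cfg = sim_config(n_snp = 50, beta_causal = 0.1, seed = 2203,
                     pleiotropy_mode = "balanced", pleiotropy_sd = 0.003),
    methods = c("ivw_re", "ivw_fe"),
    selection = selection_config(p_threshold = 5e-8, outcome_p_exclude = 0)),
  directional_pleiotropy = list(
    cfg = sim_config(n_snp = 50, beta_causal = 0.1, seed = 2204,
                     pleiotropy_mode = "directional", pleiotropy_mean = 0.02,
                     pleiotropy_sd = 0.005),
    methods = c("ivw_re", "egger", "egger_intercept"),
    selection = selection_config(p_threshold = 5e-8, outcome_p_exclude = 0))
)

tables <- lapply(names(studies), function(name) {
  s <- studies[[name]]
  cal <- calibration_study(s$cfg, n_reps = n_reps, methods = s$methods,
                           selection = s$selection, n_boot = 200)
  cal$scenario <- name
  cal
})
cal <- do.call(rbind, tables)
cal <- cal[c("scenario", setdiff(names(cal), "scenario"))]
write.table(cal, file.path("results", "calibration.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
print(cal, digits = 3)

cat("\nReadings: under the null the IVW rejection rate should sit near the
nominal 0.05; under a true effect of 0.1 the mean estimates should center
on 0.1 with ~0.95 coverage; under balanced pleiotropy random-effects
coverage should dominate fixed-effects; under directional pleiotropy the
Egger intercept should center on the 0.02 mean direct effect while IVW is
biased.\n")
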