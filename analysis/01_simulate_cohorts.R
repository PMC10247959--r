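#!/usr/bin/env Rscript
# Generate the synthetic two-sample GWAS datasets the downstream analyses
# consume: a panel of "immune cell count" exposures against one binary
# outcome, with known causal truth, realistic instrument strength, LD block
# structure, palindromic variants, and one null exposure as a negative
# control. Writes summary-statistics tables, LD matrices and truth side-cars
# under results/data/.

library(mrkit)

out_dir <- file.path("results", "data")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

scenarios <- list(
  monocyte_like   = list(beta = 0.06, seed = 1101),  # modest positive effect
  lymphocyte_like = list(beta = 0.00, seed = 1102),  # true null
  neutrophil_like = list(beta = 0.03, seed = 1103)   # weak positive effect
)

for (label in names(scenarios)) {
  sc <- scenarios[[label]]
  cfg <- sim_config(n_snp = 120, beta_causal = sc$beta, seed = sc$seed,
                    prop_palindromic = 0.15,
                    ld_blocks = list(c(6, 0.9), c(4, 0.6), c(5, 0.3)))
  sim <- simulate_pair(cfg)
  write_sumstats(sim$exposure, file.path(out_dir, paste0(label, "_exposure.tsv")))
  write_sumstats(sim$outcome, file.path(out_dir, paste0(label, "_outcome.tsv")))
  write_ld_matrix(sim$ld,
                  file.path(out_dir, paste0(label, "_ld_info.tsv")),
                  file.path(out_dir, paste0(label, "_ld_matrix.tsv")))
  write_sim_truth(sim$truth, file.path(out_dir, paste0(label, "_truth.tsv")))
  cat(sprintf("%s: %d SNPs, true causal effect %.2f (OR %.3f)\n",
              label, cfg$n_snp, sc$beta, exp(sc$beta)))
}

cat("wrote synthetic cohorts to", out_dir, "\n")
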