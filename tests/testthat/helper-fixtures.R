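# Shared fixture builders and independent oracles used across test files.
# Everything is generated in code; no stored data.

# A valid random summary-statistics table (uncorrelated fields).
make_sumstats <- function(n, seed = 1, trait_label = "test trait",
                          with_missing_eaf = FALSE) {
  set.seed(seed)
  alleles <- rbind(c("A", "G"), c("C", "T"), c("A", "C"), c("G", "T"),
                   c("A", "T"), c("C", "G"))
  pick <- alleles[sample.int(nrow(alleles), n, replace = TRUE), , drop = FALSE]
  beta <- rnorm(n, 0, 0.05)
  se <- runif(n, 0.001, 0.02)
  eaf <- runif(n, 0.01, 0.99)
  if (with_missing_eaf) eaf[sample.int(n, max(1, n %/% 5))] <- NA
  sumstats_table(data.frame(
    snp_id = sprintf("rs%05d", sample.int(99999, n)),
    chrom = as.character(sample.int(3, n, replace = TRUE)),
    pos = sample.int(5e7, n),
    effect_allele = pick[, 1], other_allele = pick[, 2],
    eaf = eaf, beta = beta, se = se,
    pvalue = pvalue_from_z(beta, se),
    n = sample.int(5e5, n), stringsAsFactors = FALSE),
    trait_label = trait_label)
}

# Random clumping instance: n SNPs on few chromosomes with a dense random
# r-squared structure (squared correlation matrix of gaussian noise).
make_clump_instance <- function(n, seed) {
  set.seed(seed)
  x <- matrix(rnorm((n + 2) * n), ncol = n)
  r2 <- stats::cor(x)^2
  snp_id <- sprintf("rs%03d", seq_len(n))
  chrom <- as.character(sample.int(3, n, replace = TRUE))
  pos <- sample.int(3e6, n)  # many pairs inside a 1000-kb window
  beta <- rnorm(n, 0, 0.05)
  se <- runif(n, 0.001, 0.02)
  tbl <- sumstats_table(data.frame(
    snp_id = snp_id, chrom = chrom, pos = pos,
    effect_allele = "A", other_allele = "G",
    eaf = runif(n, 0.05, 0.95), beta = beta, se = se,
    pvalue = pvalue_from_z(beta, se), n = NA_integer_,
    stringsAsFactors = FALSE))
  list(table = tbl, ld = ld_matrix(snp_id, chrom, pos, r2))
}

# Independent brute-force clumping oracle: after every index selection the
# remaining pool is fully re-sorted and re-scanned.
oracle_clump <- function(table, ld, r2_threshold, window_kb) {
  pool <- as.data.frame(table)
  kept <- character(0)
  while (nrow(pool) > 0) {
    pool <- pool[order(pool$pvalue, pool$chrom, pool$pos, pool$snp_id), ,
                 drop = FALSE]
    idx <- pool[1, ]
    kept <- c(kept, idx$snp_id)
    survive <- logical(nrow(pool))
    for (i in seq_len(nrow(pool))) {
      if (i == 1) next
      same_chr <- pool$chrom[i] == idx$chrom
      in_win <- abs(pool$pos[i] - idx$pos) <= window_kb * 1000
      r2 <- ld$r2[idx$snp_id, pool$snp_id[i]]
      survive[i] <- !(same_chr && in_win && r2 >= r2_threshold)
    }
    pool <- pool[survive, , drop = FALSE]
  }
  kept
}

# Harmonized instrument set built directly from effect vectors.
make_instruments <- function(bx, by, sx = 0.002, sy = 0.01,
                             snp_id = sprintf("rs%03d", seq_along(bx))) {
  data.frame(snp_id = snp_id,
             effect_allele = "A", other_allele = "G",
             eaf_exposure = 0.3,
             beta_exposure = bx, se_exposure = rep_len(sx, length(bx)),
             pvalue_exposure = pvalue_from_z(bx, rep_len(sx, length(bx))),
             beta_outcome = by, se_outcome = rep_len(sy, length(bx)),
             pvalue_outcome = pvalue_from_z(by, rep_len(sy, length(bx))),
             stringsAsFactors = FALSE)
}

# Random harmonized instrument set for property checks.
make_random_instruments <- function(n, seed, heterogeneous = TRUE) {
  set.seed(seed)
  bx <- abs(rnorm(n, 0, 0.02)) + 0.005
  slope <- rnorm(1, 0, 0.2)
  sy <- runif(n, 0.002, 0.01)
  by <- slope * bx + if (heterogeneous) rnorm(n, 0, 0.01) else 0
  make_instruments(bx, by, sx = runif(n, 0.001, 0.004), sy = sy)
}

# Weighted-least-squares oracle via lm(): origin fit and free-intercept fit.
oracle_wls_origin <- function(inst) {
  fit <- lm(beta_outcome ~ 0 + beta_exposure, data = inst,
            weights = 1 / inst$se_outcome^2)
  list(beta = unname(coef(fit)[1]),
       se_fixed = unname(sqrt(diag(vcov(fit)) / summary(fit)$sigma^2)))
}

oracle_wls_egger <- function(inst) {
  flip <- inst$beta_exposure < 0
  d <- data.frame(bx = abs(inst$beta_exposure),
                  by = ifelse(flip, -inst$beta_outcome, inst$beta_outcome),
                  w = 1 / inst$se_outcome^2)
  fit <- lm(by ~ bx, data = d, weights = d$w)
  unscaled <- sqrt(diag(vcov(fit))) / summary(fit)$sigma
  scale <- max(1, summary(fit)$sigma)
  list(intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
       intercept_se = unname(unscaled[1] * scale),
       slope_se = unname(unscaled[2] * scale))
}
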