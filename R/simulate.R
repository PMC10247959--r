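#' Configuration for the synthetic two-sample GWAS generator
#'
#' Encodes the standard two-sample MR data model: per-SNP true exposure
#' effects `gamma_j ~ N(0, gamma_sd^2)` are fixed truth; the observed
#' summary statistics are independent draws
#' `beta_hat_X ~ N(gamma_j, se_exposure^2)` and
#' `beta_hat_Y ~ N(beta_causal * gamma_j + alpha_j, se_outcome^2)`, with
#' direct (pleiotropic) outcome effects `alpha_j` all zero (`none`), drawn
#' `N(0, pleiotropy_sd^2)` (`balanced`, InSIDE holds), or
#' `N(pleiotropy_mean, pleiotropy_sd^2)` (`directional`).
#'
#' Default sampling SEs mirror the scale of the source studies this design
#' emulates: `se_exposure = 0.002` (per-allele SE of a quantitative blood
#' trait at n ~ 5.6e5 and typical MAF) and `se_outcome = 0.003` (log-odds
#' SE at the effective size of a 74k-case / 824k-control GWAS);
#' `gamma_sd = 0.02` puts per-allele exposure effects in the range of blood
#' cell trait loci, giving a mean instrument F of ~100.
#'
#' @param n_snp Number of candidate instruments.
#' @param beta_causal True causal effect of exposure on outcome (log-odds
#'   per SD for a binary outcome).
#' @param gamma_sd SD of the true SNP-to-exposure effects.
#' @param se_exposure,se_outcome Sampling SEs, scalar or per-SNP vectors.
#' @param pleiotropy_mode `"none"`, `"balanced"` or `"directional"`.
#' @param pleiotropy_sd SD of direct outcome effects.
#' @param pleiotropy_mean Mean direct effect (nonzero only for directional).
#' @param prop_palindromic Fraction of SNPs assigned A/T or C/G alleles.
#' @param ld_blocks Optional list of `c(size, r2)` pairs: consecutive SNPs
#'   are grouped into blocks of the given sizes with the given within-block
#'   r-squared (between-block r-squared 0); remaining SNPs are independent.
#' @param seed Integer seed; all output is a pure function of the config.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_snp = 50, beta_causal = 0, gamma_sd = 0.02,
                       se_exposure = 0.002, se_outcome = 0.003,
                       pleiotropy_mode = c("none", "balanced", "directional"),
                       pleiotropy_sd = 0, pleiotropy_mean = 0,
                       prop_palindromic = 0.1, ld_blocks = NULL, seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(n_snp >= 1, gamma_sd > 0, all(se_exposure > 0),
            all(se_outcome > 0), pleiotropy_sd >= 0,
            prop_palindromic >= 0, prop_palindromic <= 1)
  if (pleiotropy_mode != "directional" && pleiotropy_mean != 0) {
    stop("pleiotropy_mean must be 0 unless pleiotropy_mode is 'directional'")
  }
  if (pleiotropy_mode == "none" && pleiotropy_sd != 0) {
    stop("pleiotropy_sd must be 0 when pleiotropy_mode is 'none'")
  }
  structure(list(n_snp = as.integer(n_snp), beta_causal = beta_causal,
                 gamma_sd = gamma_sd, se_exposure = se_exposure,
                 se_outcome = se_outcome, pleiotropy_mode = pleiotropy_mode,
                 pleiotropy_sd = pleiotropy_sd,
                 pleiotropy_mean = pleiotropy_mean,
                 prop_palindromic = prop_palindromic,
                 ld_blocks = ld_blocks, seed = as.integer(seed)),
            class = "sim_config")
}

NONPALINDROMIC_PAIRS <- rbind(c("A", "C"), c("A", "G"), c("C", "A"),
                              c("C", "T"), c("G", "A"), c("G", "T"),
                              c("T", "C"), c("T", "G"))
PALINDROMIC_PAIRS <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

#' Simulate a matched exposure/outcome summary-statistics pair
#'
#' Deterministic given the config seed. Positions are spaced so that LD
#' blocks fall inside the default clumping window (block members 10 kb
#' apart) while unlinked SNPs sit on alternating chromosome arms far beyond
#' it. p-values are computed from each beta/SE; EAFs are drawn uniform on
#' (0.05, 0.95); the configured palindromic fraction receives A/T or C/G
#' allele pairs. Outcome records share snp_id, position, alleles and EAF
#' with the exposure (same variants read in a second, non-overlapping
#' sample).
#'
#' @param cfg A [sim_config()].
#' @return List with `exposure` and `outcome` (`sumstats` tables), `ld`
#'   (an [ld_matrix()]), and `truth` (list `beta_causal`, `gamma`, `alpha`,
#'   `seed`).
#' @export
simulate_pair <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_local_seed(cfg$seed, {
    n <- cfg$n_snp
    # Effect alleles are oriented to the exposure-increasing allele (the
    # convention harmonized MR tables use), so true exposure effects are
    # half-normal; this is also what makes a *directional* mean direct
    # effect well defined, since reorienting an allele flips gamma and
    # alpha together.
    gamma <- abs(stats::rnorm(n, 0, cfg$gamma_sd))
    alpha <- switch(cfg$pleiotropy_mode,
      none = rep(0, n),
      balanced = stats::rnorm(n, 0, cfg$pleiotropy_sd),
      directional = stats::rnorm(n, cfg$pleiotropy_mean, cfg$pleiotropy_sd))
    se_x <- rep_len(cfg$se_exposure, n)
    se_y <- rep_len(cfg$se_outcome, n)
    bx <- stats::rnorm(n, gamma, se_x)
    by <- stats::rnorm(n, cfg$beta_causal * gamma + alpha, se_y)
    eaf <- stats::runif(n, 0.05, 0.95)

    n_pal <- round(cfg$prop_palindromic * n)
    pal_idx <- if (n_pal > 0) sample.int(n, n_pal) else integer(0)
    alleles <- NONPALINDROMIC_PAIRS[
      sample.int(nrow(NONPALINDROMIC_PAIRS), n, replace = TRUE), , drop = FALSE]
    if (n_pal > 0) {
      alleles[pal_idx, ] <- PALINDROMIC_PAIRS[
        sample.int(nrow(PALINDROMIC_PAIRS), n_pal, replace = TRUE), ,
        drop = FALSE]
    }

    # LD layout: blocks occupy consecutive SNPs 10 kb apart; everything
    # else is placed >= 10 Mb away (outside any clumping window) across
    # chromosomes 1..22.
    r2 <- diag(n)
    block_id <- rep(0L, n)
    if (!is.null(cfg$ld_blocks)) {
      at <- 1L
      for (b in seq_along(cfg$ld_blocks)) {
        size <- as.integer(cfg$ld_blocks[[b]][1])
        rho2 <- cfg$ld_blocks[[b]][2]
        stopifnot(size >= 1, rho2 >= 0, rho2 <= 1)
        if (at + size - 1L > n) stop("ld_blocks exceed n_snp")
        members <- at:(at + size - 1L)
        r2[members, members] <- rho2
        diag(r2)[members] <- 1
        block_id[members] <- b
        at <- at + size
      }
    }
    chrom <- as.character(rep_len(1:22, n))
    # Unlinked SNPs (r2 = 0) are never clumped whatever their spacing; give
    # them 100-kb spacing, and pack block members 10 kb apart on one
    # chromosome so blocks sit inside the default clumping window.
    pos <- seq_len(n) * 100000L
    if (any(block_id > 0)) {
      for (b in unique(block_id[block_id > 0])) {
        members <- which(block_id == b)
        chrom[members] <- chrom[members[1]]
        pos[members] <- pos[members[1]] + (seq_along(members) - 1L) * 10000L
      }
    }
    snp_id <- sprintf("rs%06d", seq_len(n))

    exposure <- sumstats_table(data.frame(
      snp_id = snp_id, chrom = chrom, pos = pos,
      effect_allele = alleles[, 1], other_allele = alleles[, 2],
      eaf = eaf, beta = bx, se = se_x, pvalue = pvalue_from_z(bx, se_x),
      n = NA_integer_, stringsAsFactors = FALSE),
      trait_label = "simulated exposure", trait_type = "quantitative")
    outcome <- sumstats_table(data.frame(
      snp_id = snp_id, chrom = chrom, pos = pos,
      effect_allele = alleles[, 1], other_allele = alleles[, 2],
      eaf = eaf, beta = by, se = se_y, pvalue = pvalue_from_z(by, se_y),
      n = NA_integer_, stringsAsFactors = FALSE),
      trait_label = "simulated outcome", trait_type = "binary")
    ld <- ld_matrix(snp_id, chrom, pos, r2)
    truth <- list(beta_causal = cfg$beta_causal, gamma = gamma,
                  alpha = alpha, seed = cfg$seed)
    list(exposure = exposure, outcome = outcome, ld = ld, truth = truth)
  })
}

#' Write the generating truth of a simulated pair as a side-car TSV
#' @param truth The `truth` element of [simulate_pair()].
#' @param path Output path.
#' @export
write_sim_truth <- function(truth, path) {
  df <- data.frame(snp_index = seq_along(truth$gamma),
                   gamma = fmt_num(truth$gamma),
                   alpha = fmt_num(truth$alpha))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# beta_causal\t%.17g", truth$beta_causal), con)
  writeLines(sprintf("# seed\t%d", truth$seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Monte-Carlo calibration of the estimator suite
#'
#' For each replicate: simulate a two-sample pair with a fresh substream
#' seed, run the full selection (significance filter, LD clumping,
#' F screen, outcome-overlap exclusion), harmonize, and apply the requested
#' estimators. Tabulates per method the rejection rate at `alpha`, mean
#' estimate, empirical SE, mean reported SE, and 95% CI coverage of the
#' true causal effect. The pseudo-method `egger_intercept` tracks the
#' Egger intercept against the true mean pleiotropic effect.
#'
#' @param cfg A [sim_config()]; `cfg$seed` drives per-replicate substream
#'   seeds so replicates are independent yet individually reproducible.
#' @param n_reps Number of replicates.
#' @param alpha Nominal test size.
#' @param methods Subset of `c("ivw_re", "ivw_fe", "weighted_median",
#'   "egger", "egger_intercept")`.
#' @param selection A [selection_config()]; the default relaxes the
#'   significance threshold to genome-wide 5e-8 (the simulator's modest
#'   per-SNP effects correspond to that regime).
#' @param harmonize_cfg A [harmonize_config()].
#' @param n_boot Bootstrap replicates for the weighted median.
#' @return data.frame, one row per method: `method`, `n_reps_used`,
#'   `rejection_rate`, `mean_estimate`, `empirical_se`, `mean_se`,
#'   `coverage`, `mean_n_snp`, `truth`.
#' @export
calibration_study <- function(cfg, n_reps, alpha = 0.05,
                              methods = c("ivw_re", "weighted_median",
                                          "egger", "egger_intercept"),
                              selection = selection_config(p_threshold = 5e-8),
                              harmonize_cfg = harmonize_config(),
                              n_boot = 200) {
  stopifnot(inherits(cfg, "sim_config"), n_reps >= 1)
  methods <- match.arg(methods, several.ok = TRUE,
                       choices = c("ivw_re", "ivw_fe", "weighted_median",
                                   "egger", "egger_intercept"))
  rep_seeds <- with_local_seed(cfg$seed,
                               sample.int(.Machine$integer.max - 1L, n_reps))
  acc <- lapply(methods, function(m) {
    list(est = numeric(0), se = numeric(0), n_snp = integer(0))
  })
  names(acc) <- methods

  for (r in seq_len(n_reps)) {
    rcfg <- cfg
    rcfg$seed <- rep_seeds[r]
    sim <- simulate_pair(rcfg)
    inst <- select_instruments(sim$exposure, sim$outcome, sim$ld, selection)
    if (nrow(inst) == 0) next
    h <- harmonize(inst, sim$outcome, harmonize_cfg)$instruments
    k <- nrow(h)
    if (k < 3) next
    for (m in methods) {
      res <- switch(m,
        ivw_re = { e <- ivw(h, "random")$estimate; c(e$beta, e$se) },
        ivw_fe = { e <- ivw(h, "fixed")$estimate; c(e$beta, e$se) },
        weighted_median = {
          e <- weighted_median(h, n_boot = n_boot, seed = rep_seeds[r] %% 1000003L)
          c(e$beta, e$se)
        },
        egger = { e <- egger(h)$slope; c(e$beta, e$se) },
        egger_intercept = { e <- egger(h); c(e$intercept, e$intercept_se) })
      acc[[m]]$est <- c(acc[[m]]$est, res[1])
      acc[[m]]$se <- c(acc[[m]]$se, res[2])
      acc[[m]]$n_snp <- c(acc[[m]]$n_snp, k)
    }
  }

  z <- stats::qnorm(1 - alpha / 2)
  z95 <- stats::qnorm(0.975)
  rows <- lapply(methods, function(m) {
    truth <- if (m == "egger_intercept") {
      if (cfg$pleiotropy_mode == "directional") cfg$pleiotropy_mean else 0
    } else cfg$beta_causal
    est <- acc[[m]]$est; se <- acc[[m]]$se
    data.frame(
      method = m, n_reps_used = length(est),
      rejection_rate = mean(abs(est / se) > z),
      mean_estimate = mean(est),
      empirical_se = stats::sd(est),
      mean_se = mean(se),
      coverage = mean(abs(est - truth) <= z95 * se),
      mean_n_snp = mean(acc[[m]]$n_snp),
      truth = truth, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
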