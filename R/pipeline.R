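METHOD_ORDER <- c("ivw_re", "ivw_fe", "weighted_median", "egger_slope",
                  "wald_ratio", "none")

report_row <- function(exposure, outcome, method, subset, est = NULL,
                       het = NULL, egger_intercept = NA_real_,
                       egger_intercept_pvalue = NA_real_, bonferroni_m = 6) {
  tier <- NA_character_
  if (!is.null(est)) {
    tier <- if (est$pvalue < 0.05 / bonferroni_m) "bonferroni_significant"
            else if (est$pvalue < 0.05) "nominal" else "null"
  }
  data.frame(
    exposure = exposure, outcome = outcome,
    method = method, subset = subset,
    n_snp = if (is.null(est)) 0L else est$n_snp,
    beta = if (is.null(est)) NA_real_ else est$beta,
    se = if (is.null(est)) NA_real_ else est$se,
    or = if (is.null(est)) NA_real_ else est$odds_ratio,
    or_ci_low = if (is.null(est)) NA_real_ else est$or_ci_low,
    or_ci_high = if (is.null(est)) NA_real_ else est$or_ci_high,
    pvalue = if (is.null(est)) NA_real_ else est$pvalue,
    Q = if (is.null(het)) NA_real_ else het$Q,
    Q_df = if (is.null(het)) NA_integer_ else as.integer(het$df),
    Q_pvalue = if (is.null(het)) NA_real_ else het$pvalue,
    egger_intercept = egger_intercept,
    egger_intercept_pvalue = egger_intercept_pvalue,
    tier = tier, stringsAsFactors = FALSE)
}

#' Full MR analysis of one harmonized exposure-outcome pair
#'
#' Estimator branching follows the instrument count: a single instrument
#' yields a Wald ratio only; two give IVW plus Cochran's Q; three or more
#' give the full suite — random-effects IVW (primary), weighted median,
#' MR-Egger slope and intercept test, Cochran's Q, radial outlier detection
#' with post-removal IVW, and leave-one-out.
#'
#' @param harmonized Harmonized instrument data.frame (see [harmonize()]).
#' @param exposure_label,outcome_label Labels for the report rows.
#' @param n_boot,seed Weighted-median bootstrap settings.
#' @param outlier_alpha Radial per-SNP outlier level.
#' @param bonferroni_m Number of tests sharing the Bonferroni family
#'   (significance tier threshold 0.05/m).
#' @return List with `rows` (report data.frame), `loo` (leave-one-out table
#'   or NULL) and `radial` (radial result or NULL).
#' @export
mr_analysis <- function(harmonized, exposure_label = "exposure",
                        outcome_label = "outcome", n_boot = 1000, seed = 1L,
                        outlier_alpha = 0.05, bonferroni_m = 6) {
  k <- nrow(harmonized)
  if (k == 0) {
    return(list(rows = report_row(exposure_label, outcome_label, "none",
                                  "no valid instruments",
                                  bonferroni_m = bonferroni_m),
                loo = NULL, radial = NULL))
  }
  if (k == 1) {
    est <- wald_ratio(harmonized)
    return(list(rows = report_row(exposure_label, outcome_label,
                                  "wald_ratio", "all", est,
                                  bonferroni_m = bonferroni_m),
                loo = NULL, radial = NULL))
  }
  ivw_res <- ivw(harmonized, "random")
  rows <- report_row(exposure_label, outcome_label, "ivw_re", "all",
                     ivw_res$estimate, ivw_res$heterogeneity,
                     bonferroni_m = bonferroni_m)
  loo <- NULL
  radial <- NULL
  if (k >= 3) {
    wm <- weighted_median(harmonized, n_boot = n_boot, seed = seed)
    eg <- egger(harmonized)
    rows$egger_intercept <- eg$intercept
    rows$egger_intercept_pvalue <- eg$intercept_pvalue
    radial <- radial_ivw(harmonized, outlier_alpha = outlier_alpha)
    rows <- rbind(
      rows,
      report_row(exposure_label, outcome_label, "weighted_median", "all",
                 wm, bonferroni_m = bonferroni_m),
      report_row(exposure_label, outcome_label, "egger_slope", "all",
                 eg$slope, eg$Q, eg$intercept, eg$intercept_pvalue,
                 bonferroni_m = bonferroni_m))
    if (any(radial$outlier) && !all(radial$outlier)) {
      post <- remove_outliers_and_reestimate(harmonized, radial)
      rows <- rbind(rows,
                    report_row(exposure_label, outcome_label, "ivw_re",
                               "outlier_removed", post$estimate,
                               post$heterogeneity,
                               bonferroni_m = bonferroni_m))
    }
    loo <- leave_one_out(harmonized)
  }
  list(rows = rows, loo = loo, radial = radial)
}

#' Rerun the IVW after removing listed confounder-associated instruments
#'
#' @param harmonized Harmonized instrument data.frame.
#' @param exclusion_ids snp_ids to remove (e.g. variants with suggestive
#'   associations to known outcome risk factors).
#' @param exposure_label,outcome_label,bonferroni_m Report settings.
#' @return One report row (subset `"confounder_pruned"`), or a
#'   "no valid instruments" row if nothing survives.
#' @export
rerun_without_confounder_snps <- function(harmonized, exclusion_ids,
                                          exposure_label = "exposure",
                                          outcome_label = "outcome",
                                          bonferroni_m = 6) {
  keep <- !harmonized$snp_id %in% exclusion_ids
  mr_log("confounder pruning: removed ", sum(!keep), " of ", nrow(harmonized))
  pruned <- harmonized[keep, , drop = FALSE]
  if (nrow(pruned) == 0) {
    return(report_row(exposure_label, outcome_label, "none",
                      "confounder_pruned", bonferroni_m = bonferroni_m))
  }
  if (nrow(pruned) == 1) {
    return(report_row(exposure_label, outcome_label, "wald_ratio",
                      "confounder_pruned", wald_ratio(pruned),
                      bonferroni_m = bonferroni_m))
  }
  res <- ivw(pruned, "random")
  report_row(exposure_label, outcome_label, "ivw_re", "confounder_pruned",
             res$estimate, res$heterogeneity, bonferroni_m = bonferroni_m)
}

#' End-to-end MR run for one or more exposures against one outcome
#'
#' For each exposure: select instruments ([select_instruments()]),
#' harmonize against the outcome, run [mr_analysis()], and optionally the
#' confounder-pruned IVW. Exposures left with zero instruments are reported
#' as "no valid instruments" and the run continues. Deterministic given the
#' configuration (all seeds explicit). Input tables are never modified.
#'
#' @param exposures Named list of `sumstats` tables (names label the report).
#' @param outcome A `sumstats` table.
#' @param ld_list Named list of [ld_matrix()] objects, parallel to
#'   `exposures` (a single `ld_matrix` is recycled).
#' @param selection A [selection_config()] or named list of them.
#' @param harmonize_cfg A [harmonize_config()].
#' @param outcome_label Label for the outcome.
#' @param n_boot,seed,outlier_alpha,bonferroni_m Estimator settings.
#' @param exclusion_ids Optional character vector (or named list per
#'   exposure) of confounder-associated snp_ids.
#' @return List with `rows` (combined report data.frame), `harmonized`
#'   (named list of harmonized tables), `loo` and `radial` (named lists).
#' @export
run_mr <- function(exposures, outcome, ld_list,
                   selection = selection_config(),
                   harmonize_cfg = harmonize_config(),
                   outcome_label = "outcome", n_boot = 1000, seed = 1L,
                   outlier_alpha = 0.05, bonferroni_m = 6,
                   exclusion_ids = NULL) {
  if (inherits(exposures, "sumstats")) exposures <- list(exposure = exposures)
  if (is.null(names(exposures))) {
    names(exposures) <- paste0("exposure_", seq_along(exposures))
  }
  if (inherits(ld_list, "ld_matrix")) {
    ld_list <- stats::setNames(rep(list(ld_list), length(exposures)),
                               names(exposures))
  }
  get_cfg <- function(obj, label, class) {
    if (inherits(obj, class)) obj else obj[[label]]
  }
  all_rows <- list()
  harmonized <- list()
  loo <- list()
  radial <- list()
  for (label in names(exposures)) {
    sel <- get_cfg(selection, label, "selection_config")
    inst <- select_instruments(exposures[[label]], outcome,
                               ld_list[[label]], sel)
    h <- harmonize(inst, outcome, harmonize_cfg)$instruments
    harmonized[[label]] <- h
    res <- mr_analysis(h, exposure_label = label,
                       outcome_label = outcome_label, n_boot = n_boot,
                       seed = seed, outlier_alpha = outlier_alpha,
                       bonferroni_m = bonferroni_m)
    rows <- res$rows
    if (!is.null(exclusion_ids) && nrow(h) > 0) {
      excl <- if (is.list(exclusion_ids)) exclusion_ids[[label]]
              else exclusion_ids
      if (length(excl) > 0) {
        rows <- rbind(rows, rerun_without_confounder_snps(
          h, excl, exposure_label = label, outcome_label = outcome_label,
          bonferroni_m = bonferroni_m))
      }
    }
    all_rows[[label]] <- rows
    loo[[label]] <- res$loo
    radial[[label]] <- res$radial
  }
  list(rows = do.call(rbind, c(all_rows, list(make.row.names = FALSE))),
       harmonized = harmonized, loo = loo, radial = radial)
}

fmt_round <- function(x, digits) {
  ifelse(is.na(x), "NA", formatC(round(x, digits), format = "f",
                                 digits = digits))
}

#' Render MR report rows as an aligned forest-style text table
#'
#' One line per (exposure, subset, method), canonically sorted (exposure,
#' subset, method order IVW / weighted median / Egger / Wald). Odds ratios
#' and CI bounds are rounded half-to-even to `or_digits` decimals,
#' p-values to `p_digits`.
#'
#' @param rows Report data.frame from [run_mr()] / [mr_analysis()].
#' @param or_digits,p_digits Decimal places.
#' @return Character vector of report lines (header first), invisibly also
#'   suitable for `writeLines`.
#' @export
render_forest_table <- function(rows, or_digits = 2, p_digits = 4) {
  stopifnot(nrow(rows) >= 1)
  ord <- order(rows$exposure, rows$subset,
               match(rows$method, METHOD_ORDER))
  rows <- rows[ord, , drop = FALSE]
  body <- data.frame(
    exposure = rows$exposure,
    outcome = rows$outcome,
    method = rows$method,
    subset = rows$subset,
    n_snp = as.character(rows$n_snp),
    or_ci = ifelse(is.na(rows$or), "NA",
                   sprintf("%s (%s-%s)", fmt_round(rows$or, or_digits),
                           fmt_round(rows$or_ci_low, or_digits),
                           fmt_round(rows$or_ci_high, or_digits))),
    p = fmt_round(rows$pvalue, p_digits),
    Q_p = fmt_round(rows$Q_pvalue, p_digits),
    egger_int_p = fmt_round(rows$egger_intercept_pvalue, p_digits),
    tier = ifelse(is.na(rows$tier), "NA", rows$tier),
    stringsAsFactors = FALSE)
  header <- c("exposure", "outcome", "method", "subset", "n_snp",
              "OR (95% CI)", "p", "Q_p", "egger_intercept_p", "tier")
  mat <- rbind(header, as.matrix(body))
  widths <- apply(nchar(mat), 2, max)
  lines <- apply(mat, 1, function(r) {
    paste(mapply(formatC, r, width = widths, flag = "-"), collapse = "  ")
  })
  trimws(lines, which = "right")
}

#' Write report rows as a tidy TSV
#' @param rows Report data.frame.
#' @param path Output path.
#' @export
write_report <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
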