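# Run code under a temporary RNG state so estimator calls with an explicit
# seed never disturb the caller's random stream.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Construct a causal-effect estimate record
#'
#' Normal-based 95% confidence interval on the beta (log-odds) scale,
#' two-sided normal p-value, and the exponentiated odds-ratio scale.
#'
#' @param method Estimator label (`wald_ratio`, `ivw_fe`, `ivw_re`,
#'   `weighted_median`, `egger_slope`).
#' @param beta,se Point estimate and standard error (se > 0).
#' @param n_snp Number of instruments used.
#' @return List of class `mr_estimate` with fields `method`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `pvalue`, `odds_ratio`, `or_ci_low`, `or_ci_high`,
#'   `n_snp`.
#' @export
mr_estimate <- function(method, beta, se, n_snp) {
  stopifnot(is.finite(beta), is.finite(se), se > 0)
  z <- stats::qnorm(0.975)
  ci_low <- beta - z * se
  ci_high <- beta + z * se
  structure(list(method = method, beta = beta, se = se,
                 ci_low = ci_low, ci_high = ci_high,
                 pvalue = pvalue_from_z(beta, se),
                 odds_ratio = exp(beta),
                 or_ci_low = exp(ci_low), or_ci_high = exp(ci_high),
                 n_snp = as.integer(n_snp)),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s: beta = %.4g (SE %.4g), OR = %.3f (95%% CI %.3f-%.3f), p = %.3g, n_snp = %d\n",
              x$method, x$beta, x$se, x$odds_ratio, x$or_ci_low, x$or_ci_high,
              x$pvalue, x$n_snp))
  invisible(x)
}

check_instruments <- function(instruments, min_n, caller) {
  stopifnot(is.data.frame(instruments))
  need <- c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome")
  missing_cols <- setdiff(need, names(instruments))
  if (length(missing_cols) > 0) {
    stop(caller, ": missing column(s) ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(instruments) < min_n) {
    stop(caller, " requires at least ", min_n, " instrument(s), got ",
         nrow(instruments))
  }
  if (any(instruments$se_outcome <= 0) || any(instruments$se_exposure <= 0)) {
    stop(caller, ": standard errors must be positive")
  }
  invisible(instruments)
}

#' Wald ratio estimate from a single instrument
#'
#' `beta = beta_outcome / beta_exposure` with the first-order delta-method
#' standard error `se_outcome / |beta_exposure|`. With strong instruments
#' (F > 10 enforced upstream) the neglected exposure-side uncertainty is
#' second order; `second_order = TRUE` adds it:
#' `se^2 = se_Y^2/bX^2 + bY^2 se_X^2 / bX^4`.
#'
#' @param inst One-row harmonized instrument data.frame.
#' @param second_order Use the second-order delta expansion for the SE.
#' @return An [mr_estimate()] with `n_snp = 1`.
#' @export
wald_ratio <- function(inst, second_order = FALSE) {
  check_instruments(inst, 1, "wald_ratio")
  inst <- inst[1, ]
  if (inst$beta_exposure == 0) stop("degenerate instrument: beta_exposure = 0")
  beta <- inst$beta_outcome / inst$beta_exposure
  se <- inst$se_outcome / abs(inst$beta_exposure)
  if (second_order) {
    se <- sqrt(inst$se_outcome^2 / inst$beta_exposure^2 +
                 inst$beta_outcome^2 * inst$se_exposure^2 / inst$beta_exposure^4)
  }
  mr_estimate("wald_ratio", beta, se, 1L)
}

#' Inverse-variance-weighted estimate
#'
#' Weighted regression of outcome effects on exposure effects through the
#' origin with weights `1/se_outcome^2`:
#' `beta = sum(w bX bY) / sum(w bX^2)`, fixed-effects
#' `se = 1/sqrt(sum(w bX^2))`. Cochran's Q is the weighted residual sum of
#' squares with `df = n - 1`; the multiplicative random-effects model
#' inflates the SE by `max(1, sqrt(Q/df))`.
#'
#' @param instruments Harmonized instrument data.frame (>= 1 row).
#' @param model `"random"` (default, multiplicative overdispersion) or
#'   `"fixed"`.
#' @return List with `estimate` (an [mr_estimate()], method `ivw_re` or
#'   `ivw_fe`) and `heterogeneity` (list `Q`, `df`, `pvalue`).
#' @export
ivw <- function(instruments, model = c("random", "fixed")) {
  model <- match.arg(model)
  check_instruments(instruments, 1, "ivw")
  n <- nrow(instruments)
  if (n == 1) {
    est <- wald_ratio(instruments)
    est$method <- if (model == "random") "ivw_re" else "ivw_fe"
    return(list(estimate = est,
                heterogeneity = list(Q = 0, df = 0L, pvalue = 1)))
  }
  bx <- instruments$beta_exposure
  by <- instruments$beta_outcome
  w <- 1 / instruments$se_outcome^2
  beta <- sum(w * bx * by) / sum(w * bx^2)
  se_fixed <- 1 / sqrt(sum(w * bx^2))
  Q <- sum(w * (by - beta * bx)^2)
  df <- n - 1L
  het <- list(Q = Q, df = df,
              pvalue = stats::pchisq(Q, df, lower.tail = FALSE))
  se <- if (model == "random") se_fixed * max(1, sqrt(Q / df)) else se_fixed
  method <- if (model == "random") "ivw_re" else "ivw_fe"
  list(estimate = mr_estimate(method, beta, se, n), heterogeneity = het)
}

#' Cochran's Q heterogeneity statistic about a reference slope
#'
#' `Q = sum w_j (bY_j - beta_ref * bX_j)^2` with `w_j = 1/se_outcome_j^2`,
#' `df = n - 1`, upper-tail chi-square p-value.
#'
#' @param instruments Harmonized instrument data.frame (>= 2 rows).
#' @param beta_ref Reference causal slope.
#' @return List `Q`, `df`, `pvalue`.
#' @export
cochran_q <- function(instruments, beta_ref) {
  check_instruments(instruments, 2, "cochran_q")
  w <- 1 / instruments$se_outcome^2
  Q <- sum(w * (instruments$beta_outcome -
                  beta_ref * instruments$beta_exposure)^2)
  df <- nrow(instruments) - 1L
  list(Q = Q, df = df, pvalue = stats::pchisq(Q, df, lower.tail = FALSE))
}

# Weighted median of ratio estimates: order ratios ascending, take
# cumulative normalized weight minus half the current weight, and linearly
# interpolate the ratio whose cumulative weight crosses one half.
weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  wn <- weights[ord] / sum(weights)
  s <- cumsum(wn) - wn / 2
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(s)])
  k <- max(which(s < 0.5))
  r[k] + (r[k + 1] - r[k]) * (0.5 - s[k]) / (s[k + 1] - s[k])
}

#' Weighted median causal estimate
#'
#' Consistent when instruments carrying at least half the weight are valid.
#' Ratio weights are the first-order inverse variances
#' `beta_exposure^2 / se_outcome^2`; the standard error comes from a
#' parametric bootstrap (exposure and outcome effects resampled from normal
#' distributions with their reported SEs).
#'
#' @param instruments Harmonized instrument data.frame (>= 3 rows).
#' @param n_boot Bootstrap replicates.
#' @param seed RNG seed for the bootstrap (mandatory: results must be
#'   reproducible).
#' @return An [mr_estimate()] with method `weighted_median`.
#' @export
weighted_median <- function(instruments, n_boot = 1000, seed) {
  check_instruments(instruments, 3, "weighted_median")
  if (missing(seed)) stop("weighted_median requires an explicit seed")
  bx <- instruments$beta_exposure
  by <- instruments$beta_outcome
  sx <- instruments$se_exposure
  sy <- instruments$se_outcome
  point <- weighted_median_point(by / bx, bx^2 / sy^2)
  k <- length(bx)
  boots <- with_local_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bxs <- stats::rnorm(k, bx, sx)
      bys <- stats::rnorm(k, by, sy)
      weighted_median_point(bys / bxs, bxs^2 / sy^2)
    }, numeric(1))
  })
  mr_estimate("weighted_median", point, stats::sd(boots), k)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome on exposure effects with a free
#' intercept (weights `1/se_outcome^2`), after orienting all exposure
#' effects nonnegative (instruments with negative exposure beta have both
#' betas negated internally; the caller's data are not modified). A nonzero
#' intercept indicates directional pleiotropy; the slope is a
#' pleiotropy-robust causal estimate under the InSIDE assumption. Slope and
#' intercept SEs carry the multiplicative overdispersion factor
#' `max(1, sqrt(Q'/(n-2)))` where `Q'` is the weighted residual sum of
#' squares.
#'
#' @param instruments Harmonized instrument data.frame (>= 3 rows).
#' @return List with `slope` (an [mr_estimate()], method `egger_slope`),
#'   `intercept`, `intercept_se`, `intercept_pvalue`, and `Q` (residual
#'   heterogeneity `Q`, `df`, `pvalue`).
#' @export
egger <- function(instruments) {
  check_instruments(instruments, 3, "egger")
  flip <- instruments$beta_exposure < 0
  bx <- abs(instruments$beta_exposure)
  by <- ifelse(flip, -instruments$beta_outcome, instruments$beta_outcome)
  w <- 1 / instruments$se_outcome^2
  n <- length(bx)
  if (stats::var(bx) == 0) stop("singular design: no variance in exposure effects")
  # Closed-form weighted least squares for y = a + b x.
  sw <- sum(w); swx <- sum(w * bx); swy <- sum(w * by)
  swxx <- sum(w * bx^2); swxy <- sum(w * bx * by)
  det <- sw * swxx - swx^2
  intercept <- (swxx * swy - swx * swxy) / det
  slope <- (sw * swxy - swx * swy) / det
  resid <- by - intercept - slope * bx
  Qp <- sum(w * resid^2)
  df <- n - 2L
  scale <- max(1, sqrt(Qp / df))
  slope_se <- sqrt(sw / det) * scale
  intercept_se <- sqrt(swxx / det) * scale
  list(slope = mr_estimate("egger_slope", slope, slope_se, n),
       intercept = intercept, intercept_se = intercept_se,
       intercept_pvalue = pvalue_from_z(intercept, intercept_se),
       Q = list(Q = Qp, df = df,
                pvalue = stats::pchisq(Qp, df, lower.tail = FALSE)))
}

#' Radial (modified second-order weighted) IVW with per-SNP Q contributions
#'
#' Regression of `ratio_j * sqrt(w_j)` on `sqrt(w_j)` through the origin
#' with first-order ratio weights `w_j = beta_exposure^2 / se_outcome^2`.
#' The slope is algebraically identical to the IVW point estimate; the
#' per-SNP contribution `q_j = w_j (ratio_j - slope)^2` sums to the total
#' Q, and instruments whose `q_j` exceeds the upper `outlier_alpha` tail of
#' chi-square(1) are flagged as pleiotropic outliers.
#'
#' @param instruments Harmonized instrument data.frame (>= 2 rows).
#' @param outlier_alpha Per-SNP outlier significance level in (0,1); no
#'   multiplicity correction is applied by default (pass `alpha/n` for a
#'   Bonferroni-corrected screen).
#' @return List with `estimate` (an [mr_estimate()], method `ivw_re` SE on
#'   the radial scale), `Q` (total), `df`, `q_contribution` (per SNP),
#'   `outlier` (logical per SNP), `snp_id`, `outlier_alpha`.
#' @export
radial_ivw <- function(instruments, outlier_alpha = 0.05) {
  check_instruments(instruments, 2, "radial_ivw")
  stopifnot(outlier_alpha > 0, outlier_alpha < 1)
  if (any(instruments$beta_exposure == 0)) {
    stop("degenerate instrument: beta_exposure = 0")
  }
  ratio <- instruments$beta_outcome / instruments$beta_exposure
  w <- instruments$beta_exposure^2 / instruments$se_outcome^2
  slope <- sum(w * ratio) / sum(w)
  q <- w * (ratio - slope)^2
  Q <- sum(q)
  n <- length(w)
  df <- n - 1L
  se_fixed <- 1 / sqrt(sum(w))
  se <- se_fixed * max(1, sqrt(Q / df))
  outlier <- stats::pchisq(q, df = 1, lower.tail = FALSE) < outlier_alpha
  list(estimate = mr_estimate("ivw_re", slope, se, n),
       Q = Q, df = df,
       Q_pvalue = stats::pchisq(Q, df, lower.tail = FALSE),
       q_contribution = q, outlier = outlier,
       snp_id = if ("snp_id" %in% names(instruments)) instruments$snp_id
                else as.character(seq_len(n)),
       outlier_alpha = outlier_alpha)
}

#' Drop radial outliers and re-estimate
#'
#' Removes the instruments flagged by [radial_ivw()] and reruns the
#' random-effects IVW on the remainder.
#'
#' @param instruments Harmonized instrument data.frame.
#' @param radial Result of [radial_ivw()] on the same instruments.
#' @return List with `estimate`, `heterogeneity` (as [ivw()]) and
#'   `removed` (snp_ids dropped).
#' @export
remove_outliers_and_reestimate <- function(instruments, radial) {
  stopifnot(length(radial$outlier) == nrow(instruments))
  if (all(radial$outlier)) stop("all instruments flagged as outliers")
  keep <- !radial$outlier
  removed <- radial$snp_id[radial$outlier]
  mr_log("radial outlier removal: dropped ",
         paste(removed, collapse = ", "))
  out <- ivw(instruments[keep, , drop = FALSE], model = "random")
  out$removed <- removed
  out
}

#' Leave-one-out sensitivity analysis
#'
#' One random-effects IVW estimate per left-out instrument; a single
#' influential (e.g. pleiotropic) SNP shows up as the exclusion that moves
#' the estimate most.
#'
#' @param instruments Harmonized instrument data.frame (>= 3 rows).
#' @return data.frame with one row per left-out SNP: `left_out_snp_id`,
#'   `beta`, `se`, `pvalue`, `n_snp`.
#' @export
leave_one_out <- function(instruments) {
  check_instruments(instruments, 3, "leave_one_out")
  n <- nrow(instruments)
  ids <- if ("snp_id" %in% names(instruments)) instruments$snp_id
         else as.character(seq_len(n))
  rows <- lapply(seq_len(n), function(i) {
    est <- ivw(instruments[-i, , drop = FALSE], model = "random")$estimate
    data.frame(left_out_snp_id = ids[i], beta = est$beta, se = est$se,
               pvalue = est$pvalue, n_snp = est$n_snp,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
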