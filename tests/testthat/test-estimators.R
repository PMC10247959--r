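test_that("Wald ratio follows the delta-method definition", {
  inst <- make_instruments(0.1, 0.05, sy = 0.01)
  est <- wald_ratio(inst)
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.1)
  expect_equal(est$n_snp, 1L)
  expect_equal(est$odds_ratio, exp(0.5))
  expect_equal(est$or_ci_low, exp(est$ci_low))

  null_est <- wald_ratio(make_instruments(0.1, 0))
  expect_equal(null_est$beta, 0)
  expect_equal(null_est$pvalue, 1)

  expect_error(wald_ratio(make_instruments(0, 0.05)), "degenerate")

  # second-order SE incorporates exposure uncertainty and is larger
  so <- wald_ratio(make_instruments(0.1, 0.05, sx = 0.02, sy = 0.01),
                   second_order = TRUE)
  expect_gt(so$se, est$se)
  expect_equal(so$se, sqrt(0.01^2 / 0.1^2 + 0.05^2 * 0.02^2 / 0.1^4))
})

test_that("IVW reduces to the Wald ratio for one instrument and matches the closed form on three", {
  one <- make_instruments(0.1, 0.05)
  res1 <- ivw(one)
  w <- wald_ratio(one)
  expect_equal(res1$estimate$beta, w$beta)
  expect_equal(res1$estimate$se, w$se)
  expect_equal(res1$heterogeneity$Q, 0)
  expect_equal(res1$heterogeneity$df, 0L)

  three <- make_instruments(c(0.1, 0.2, 0.3), c(0.05, 0.10, 0.15), sy = 0.01)
  res3 <- ivw(three, model = "fixed")
  expect_equal(res3$estimate$beta, 0.5)
  expect_equal(res3$heterogeneity$Q, 0)
  expect_equal(res3$estimate$se, 1 / sqrt(1400))
  # collinear data: random-effects SE floored at the fixed-effects SE
  res3r <- ivw(three, model = "random")
  expect_equal(res3r$estimate$se, res3$estimate$se)

  expect_error(ivw(three[0, ]), "at least 1")
})

test_that("IVW and Egger match an independent weighted-least-squares solve to 1e-10", {
  for (seed in 1:25) {
    inst <- make_random_instruments(sample(3:40, 1), seed)
    ref <- oracle_wls_origin(inst)
    fit <- ivw(inst, model = "fixed")
    expect_equal(fit$estimate$beta, ref$beta, tolerance = 1e-10)
    expect_equal(fit$estimate$se, ref$se_fixed, tolerance = 1e-10)

    ref_e <- oracle_wls_egger(inst)
    fit_e <- egger(inst)
    expect_equal(fit_e$slope$beta, ref_e$slope, tolerance = 1e-10)
    expect_equal(fit_e$slope$se, ref_e$slope_se, tolerance = 1e-10)
    expect_equal(fit_e$intercept, ref_e$intercept, tolerance = 1e-10)
    expect_equal(fit_e$intercept_se, ref_e$intercept_se, tolerance = 1e-10)
  }
})

test_that("Cochran's Q matches hand-expanded cases and is monotone in residuals", {
  same <- make_instruments(c(0.1, 0.2, 0.4), c(0.05, 0.10, 0.20))
  q0 <- cochran_q(same, 0.5)
  expect_equal(q0$Q, 0)
  expect_equal(q0$pvalue, 1)

  # two instruments with unit ratio weight each, ratios 0 and 1
  two <- make_instruments(c(1, 1), c(0, 1), sy = 1)
  q <- cochran_q(two, 0.5)
  expect_equal(q$Q, 0.5)
  expect_equal(q$df, 1L)

  worse <- make_instruments(c(1, 1), c(0, 1.5), sy = 1)
  expect_gt(cochran_q(worse, 0.5)$Q, q$Q)
  expect_error(cochran_q(two[1, ], 0.5), "at least 2")
})

test_that("weighted median interpolates at half the weight and equals the sample median for equal weights", {
  eq <- make_instruments(c(0.1, 0.1, 0.1), c(0.01, 0.05, 0.09), sy = 0.01)
  wm <- weighted_median(eq, n_boot = 100, seed = 5)
  expect_equal(wm$beta, 0.5)

  # odd-n equal weights: exactly the ordinary median of the Wald ratios
  set.seed(77)
  bx <- rep(0.1, 9)
  by <- runif(9, -0.02, 0.08)
  oddn <- make_instruments(bx, by, sy = 0.01)
  expect_equal(weighted_median(oddn, n_boot = 50, seed = 5)$beta,
               median(by / bx))

  # a dominant instrument pins the estimate near its own ratio
  dom <- make_instruments(c(1, 0.05, 0.05), c(0.7, 0.01, 0.04), sy = 0.01)
  wmd <- weighted_median(dom, n_boot = 100, seed = 5)
  expect_equal(wmd$beta, 0.7, tolerance = 0.01)

  # order invariance and seed reproducibility
  perm <- eq[c(3, 1, 2), ]
  expect_equal(weighted_median(perm, n_boot = 100, seed = 5)$beta, wm$beta)
  expect_equal(weighted_median(eq, n_boot = 100, seed = 5)$se, wm$se)
  expect_error(weighted_median(eq[1:2, ], n_boot = 10, seed = 1), "at least 3")
  expect_error(weighted_median(eq, n_boot = 10), "seed")
})

test_that("Egger recovers an exact linear data-generating law and is orientation invariant", {
  bx <- c(0.05, 0.1, 0.2, 0.3)
  by <- 0.02 + 0.5 * bx
  inst <- make_instruments(bx, by, sy = 0.01)
  fit <- egger(inst)
  expect_equal(fit$intercept, 0.02, tolerance = 1e-12)
  expect_equal(fit$slope$beta, 0.5, tolerance = 1e-12)
  expect_equal(fit$Q$Q, 0, tolerance = 1e-20)

  # no pleiotropy (zero intercept) collinear data: slope equals IVW
  by0 <- 0.5 * bx
  inst0 <- make_instruments(bx, by0, sy = 0.01)
  expect_equal(egger(inst0)$slope$beta, ivw(inst0)$estimate$beta,
               tolerance = 1e-12)

  # negating one instrument's exposure AND outcome effects changes nothing
  flipped <- inst
  flipped$beta_exposure[2] <- -flipped$beta_exposure[2]
  flipped$beta_outcome[2] <- -flipped$beta_outcome[2]
  fit_f <- egger(flipped)
  expect_equal(fit_f$slope$beta, fit$slope$beta)
  expect_equal(fit_f$intercept, fit$intercept)

  expect_error(egger(inst[1:2, ]), "at least 3")
  expect_error(egger(make_instruments(rep(0.1, 3), c(0.1, 0.2, 0.3))),
               "singular")
})

test_that("radial slope is numerically identical to IVW under first-order weights", {
  for (seed in 1:25) {
    inst <- make_random_instruments(sample(2:40, 1), seed + 100)
    rad <- radial_ivw(inst)
    # IVW with weights 1/se_outcome^2 regressing by on bx through the origin
    # equals the radial fit with ratio weights bx^2/se_outcome^2
    expect_equal(rad$estimate$beta, ivw(inst, "fixed")$estimate$beta,
                 tolerance = 1e-10)
    expect_equal(sum(rad$q_contribution), rad$Q, tolerance = 1e-8)
  }
})

test_that("radial outlier flags isolate a planted contaminated instrument", {
  set.seed(55)
  n <- 20
  bx <- abs(rnorm(n, 0, 0.02)) + 0.01
  by <- 0.1 * bx + rnorm(n, 0, 0.0005)
  inst <- make_instruments(bx, by, sy = 0.005)
  clean <- radial_ivw(inst)
  expect_true(all(clean$q_contribution >= 0))
  expect_false(any(clean$outlier))

  # displace one ratio by ~10 ratio-SEs
  contaminated <- inst
  contaminated$beta_outcome[7] <- contaminated$beta_outcome[7] +
    10 * 0.005
  rad <- radial_ivw(contaminated)
  expect_true(rad$outlier[7])
  expect_equal(sum(rad$outlier), 1L)
})

test_that("outlier removal reruns IVW on the clean subset and reduces Q", {
  set.seed(56)
  n <- 20
  bx <- abs(rnorm(n, 0, 0.02)) + 0.01
  by <- 0.1 * bx + rnorm(n, 0, 0.003)
  inst <- make_instruments(bx, by, sy = 0.003)
  rad0 <- radial_ivw(inst)
  if (!any(rad0$outlier)) {
    post0 <- remove_outliers_and_reestimate(inst, rad0)
    expect_equal(post0$estimate$beta, ivw(inst)$estimate$beta)
  }
  contaminated <- inst
  contaminated$beta_outcome[3] <- contaminated$beta_outcome[3] + 0.05
  rad <- radial_ivw(contaminated)
  expect_true(rad$outlier[3])
  post <- remove_outliers_and_reestimate(contaminated, rad)
  expect_true("rs003" %in% post$removed)
  # closer to the generating slope than the contaminated fit
  expect_lt(abs(post$estimate$beta - 0.1),
            abs(ivw(contaminated)$estimate$beta - 0.1))
  expect_lt(post$heterogeneity$Q, radial_ivw(contaminated)$Q)

  all_out <- rad
  all_out$outlier <- rep(TRUE, n)
  expect_error(remove_outliers_and_reestimate(contaminated, all_out), "all")
})

test_that("leave-one-out returns one n-1 estimate per SNP and exposes single-SNP influence", {
  inst <- make_random_instruments(8, seed = 60, heterogeneous = FALSE)
  loo <- leave_one_out(inst)
  expect_equal(nrow(loo), 8L)
  expect_true(all(loo$n_snp == 7L))
  # homogeneous data: every LOO estimate equals the full-set estimate
  full <- ivw(inst)$estimate$beta
  expect_equal(loo$beta, rep(full, 8), tolerance = 1e-10)

  contaminated <- inst
  contaminated$beta_outcome[5] <- contaminated$beta_outcome[5] + 0.05
  loo_c <- leave_one_out(contaminated)
  full_c <- ivw(contaminated)$estimate$beta
  expect_equal(which.max(abs(loo_c$beta - full_c)), 5L)
  expect_error(leave_one_out(inst[1:2, ]), "at least 3")
})

test_that("estimators are scale-equivariant and invariant to instrument order", {
  inst <- make_random_instruments(12, seed = 70)
  c_scale <- 2.5
  scaled <- inst
  scaled$beta_exposure <- inst$beta_exposure * c_scale
  scaled$se_exposure <- inst$se_exposure * c_scale
  expect_equal(ivw(scaled)$estimate$beta, ivw(inst)$estimate$beta / c_scale)
  expect_equal(egger(scaled)$slope$beta, egger(inst)$slope$beta / c_scale)
  expect_equal(radial_ivw(scaled)$estimate$beta,
               radial_ivw(inst)$estimate$beta / c_scale)
  expect_equal(weighted_median(scaled, n_boot = 50, seed = 3)$beta,
               weighted_median(inst, n_boot = 50, seed = 3)$beta / c_scale)

  perm <- inst[sample.int(12), ]
  expect_equal(ivw(perm)$estimate$beta, ivw(inst)$estimate$beta)
  expect_equal(egger(perm)$intercept, egger(inst)$intercept)
  expect_equal(sort(radial_ivw(perm)$q_contribution),
               sort(radial_ivw(inst)$q_contribution))
})

test_that("random-effects SE is never below fixed-effects SE, equal iff Q <= df", {
  for (seed in 1:20) {
    inst <- make_random_instruments(sample(2:30, 1), seed + 200)
    fe <- ivw(inst, "fixed")
    re <- ivw(inst, "random")
    expect_gte(re$estimate$se, fe$estimate$se)
    if (fe$heterogeneity$Q <= fe$heterogeneity$df) {
      expect_equal(re$estimate$se, fe$estimate$se)
    } else {
      expect_gt(re$estimate$se, fe$estimate$se)
    }
  }
})
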