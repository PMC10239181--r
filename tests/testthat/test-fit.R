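test_that("degenerate unpenalized fit equals quasi-binomial logistic regression", {
  set.seed(31)
  des <- data.frame(disease = rep(c(1, 0), c(9, 4)))
  bas <- build_basis(1500, spline_spec(df = 1))
  cfg <- model_config(smoothing = "fixed", lambda = 0, tol = 1e-12,
                      variance = "quasibinomial")
  for (i in 1:10) {
    tot <- matrix(rpois(13, 40) + 5L, 1, 13)
    mm <- matrix(rbinom(13, tot, plogis(-0.4 + 0.8 * des$disease)), 1, 13)
    f <- fit_region(mm, tot, des, bas, cfg)
    g <- stats::glm(cbind(c(mm), c(tot - mm)) ~ disease,
                    family = stats::quasibinomial(), data = des)
    expect_equal(unname(f$coef), unname(coef(g)), tolerance = 1e-7)
    expect_equal(f$phi, summary(g)$dispersion, tolerance = 1e-5)
  }
})

test_that("label swap negates the disease curve and keeps the p-value", {
  set.seed(32)
  des <- data.frame(disease = rep(c(1, 0), c(9, 4)))
  des_sw <- data.frame(disease = 1 - des$disease)
  bas1 <- build_basis(1500, spline_spec(df = 1))
  cfg <- model_config(smoothing = "fixed", lambda = 0, tol = 1e-12,
                      variance = "quasibinomial")
  tot <- matrix(rpois(13, 40) + 5L, 1, 13)
  mm <- matrix(rbinom(13, tot, plogis(-0.4 + 0.8 * des$disease)), 1, 13)
  fa <- fit_region(mm, tot, des, bas1, cfg)
  fb <- fit_region(mm, tot, des_sw, bas1, cfg)
  # unpenalized likelihood: exact antisymmetry
  expect_equal(fa$curves$beta1, -fb$curves$beta1, tolerance = 1e-8)
  expect_equal(fa$region_pvalue, fb$region_pvalue, tolerance = 1e-8)

  # penalized default: near-antisymmetry (the roughness penalty is not
  # invariant under the label-swap reparameterization)
  pos <- std_positions()
  bas <- build_basis(pos)
  des2 <- std_design()
  s <- simulate_region_counts(pos, des2, beta0 = 0.2,
                              beta_disease = smooth_bump(1.2)(seq(0, 1, length.out = 60)),
                              beta_age = 0.005, seed = 7)
  des2_sw <- des2; des2_sw$disease <- 1 - des2$disease
  cfg_fix <- model_config(smoothing = "fixed", lambda = 1)
  g1 <- fit_region(s$meth, s$total, des2, bas, cfg_fix)
  g2 <- fit_region(s$meth, s$total, des2_sw, bas, cfg_fix)
  expect_gt(stats::cor(g1$curves$beta1, -g2$curves$beta1), 0.98)
  expect_true(g1$region_pvalue < 1e-6 && g2$region_pvalue < 1e-6)
})

test_that("region p-values are probabilities and withheld without convergence", {
  pos <- std_positions()
  bas <- build_basis(pos)
  des <- std_design()
  for (i in 1:5) {
    s <- simulate_region_counts(pos, des, beta0 = 0.3, beta_disease = 0.4,
                                beta_age = 0.005, seed = i)
    f <- fit_region(s$meth, s$total, des, bas)
    expect_gte(f$region_pvalue, 0)
    expect_lte(f$region_pvalue, 1)
  }
  s <- simulate_region_counts(pos, des, beta0 = 0.3, seed = 1)
  f_nc <- fit_region(s$meth, s$total, des, bas,
                     model_config(max_iter = 1L, tol = 1e-14))
  expect_false(f_nc$converged)
  expect_error(region_test(f_nc), "withheld")
  expect_true(is.na(f_nc$region_pvalue))
})

test_that("an all-zero methylated region yields a boundary flag, not a crash", {
  pos <- std_positions(30)
  bas <- build_basis(pos, spline_spec(df = 5))
  des <- std_design()
  tot <- matrix(20L, 30, 13)
  mm <- matrix(0L, 30, 13)
  f <- fit_region(mm, tot, des, bas)
  expect_s3_class(f, "region_fit")
  expect_true(f$boundary)
  expect_error(fit_region(mm * NA, tot, des, bas), "non-finite")
})

test_that("pointwise intervals bracket the estimate and widen with level", {
  f <- fake_fit(std_positions(10), beta0 = 0, beta1 = 0.7, se1 = 0.2)
  ci95 <- pointwise_intervals(f, 0.95)
  ci99 <- pointwise_intervals(f, 0.99)
  expect_true(all(ci95$lo <= ci95$est & ci95$est <= ci95$hi))
  expect_true(all(ci99$hi - ci99$lo > ci95$hi - ci95$lo))
  # zero SE collapses the interval onto the estimate
  f0 <- fake_fit(std_positions(5), beta0 = 0, beta1 = 0.7, se1 = 0)
  ci0 <- pointwise_intervals(f0)
  expect_equal(ci0$lo, ci0$est)
  expect_equal(ci0$hi, ci0$est)
  expect_error(pointwise_intervals(f, 1.5), "invalid")
})

test_that("empirical pointwise coverage of the disease curve is near nominal", {
  pos <- std_positions()
  bas <- build_basis(pos)
  des <- std_design()
  truth <- smooth_bump(1.5)(seq(0, 1, length.out = 60))
  interior <- 10:51
  covr <- vapply(1:200, function(i) {
    s <- simulate_region_counts(pos, des, beta0 = 0.2, beta_disease = truth,
                                beta_age = 0.005, rho = 0.05, seed = i + 999)
    ci <- pointwise_intervals(fit_region(s$meth, s$total, des, bas))
    mean(ci$lo[interior] <= truth[interior] & truth[interior] <= ci$hi[interior])
  }, numeric(1))
  expect_gte(mean(covr), 0.90)
  expect_lte(mean(covr), 0.99)
})

test_that("model-derived group proportions follow the fitted curves", {
  pos <- std_positions(10)
  # beta1 = 0: the groups coincide
  f_null <- fake_fit(pos, beta0 = 0.4, beta1 = 0, se1 = 0.1)
  fp <- fitted_group_proportions(f_null)
  expect_equal(fp$per_cpg$p_case, fp$per_cpg$p_control)
  # all coefficients zero: every proportion is exactly 0.5
  f_zero <- fake_fit(pos, beta0 = 0, beta1 = 0, se1 = 0.1)
  expect_equal(fitted_group_proportions(f_zero)$case_avg, 0.5)
  # subset averaging and the percentage-point gap
  f_eff <- fake_fit(pos, beta0 = 0.5, beta1 = -0.9, se1 = 0.1)
  fe <- fitted_group_proportions(f_eff, subset_pos = pos[3:5])
  expect_equal(fe$control_avg, plogis(0.5))
  expect_equal(fe$case_avg, plogis(-0.4))
  expect_equal(fe$gap_pp, 100 * (plogis(0.5) - plogis(-0.4)))
  expect_error(fitted_group_proportions(f_eff, subset_pos = -1), "empty")
})

test_that("bonferroni threshold is alpha over the number of regions", {
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 10), 0.005)
  expect_error(bonferroni_threshold(0.05, 0), "positive count")
})

test_that("infinite smoothing drives the disease curve to the penalty null space", {
  pos <- std_positions()
  bas <- build_basis(pos)
  des <- std_design()
  s <- simulate_region_counts(pos, des, beta0 = 0.2,
                              beta_disease = smooth_bump(1.5)(seq(0, 1, length.out = 60)),
                              beta_age = 0.005, seed = 3)
  f <- fit_region(s$meth, s$total, des, bas,
                  model_config(smoothing = "fixed", lambda = 1e9))
  b1_coef <- f$coef[f$blocks[[2]]]
  # second differences vanish: the coefficient vector is affine, so the
  # curve lies in the order-2 penalty null space
  expect_lt(max(abs(diff(b1_coef, differences = 2))), 1e-6)
})

test_that("dispersion is recovered near 1 under binomial truth", {
  pos <- std_positions()
  bas <- build_basis(pos)
  des <- std_design()
  phis <- vapply(1:200, function(i) {
    s <- simulate_region_counts(pos, des, beta0 = 0.5, beta_disease = 0,
                                beta_age = 0.005, rho = 0, seed = i + 3000)
    fit_region(s$meth, s$total, des, bas)$phi
  }, numeric(1))
  expect_gte(mean(phis), 0.85)
  expect_lte(mean(phis), 1.15)
})
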