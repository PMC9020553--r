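test_that("ML fits agree with OLS when between-participant variance is zero", {
  set.seed(101)
  d <- simulate_lmm_dataset(25, 25, 2, b = 0.4, var_intercept = 0,
                            var_residual = 1)
  fit <- fit_random_intercept(y ~ group, d)
  ols <- lm(y ~ group, d)
  expect_lt(abs(fit$coefficients$b[2] - coef(ols)[2]),
            3 * summary(ols)$coefficients[2, 2])
  expect_equal(fit$BIC, fit$k * log(fit$n) - 2 * fit$logLik)
})

test_that("a constant outcome collapses to a degenerate fit", {
  d <- data.frame(participant = factor(rep(1:6, each = 2)), y = 3)
  fit <- fit_random_intercept(y ~ 1, d)
  expect_equal(fit$coefficients$b[1], 3)
  expect_equal(fit$var_residual, 0)
})

test_that("comparing a model with itself gives chi2 = 0, p = 1, BF = 1", {
  set.seed(102)
  d <- simulate_lmm_dataset(15, 15, 2, b = 0)
  fit <- fit_random_intercept(y ~ group, d)
  cmp <- compare_models(fit, fit)
  expect_equal(cmp$chi2, 0)
  expect_equal(cmp$p, 1)
  expect_equal(cmp$bf10, 1)
  expect_equal(cmp$f2, 0)
})

test_that("the BIC Bayes factor follows its closed form", {
  # BIC_null - BIC_full = 4 -> BF10 = e^2
  f <- list(logLik = 0, BIC = 10, k = 4, n = 100,
            coefficients = data.frame(term = c("(Intercept)", "g"),
                                      b = c(0, 1), se = c(1, 1)),
            var_intercept = 1, var_residual = 1,
            fitted_fixed = rep(c(0, 1), 50), converged = TRUE)
  n <- list(logLik = -2, BIC = 14, k = 3, n = 100,
            coefficients = data.frame(term = "(Intercept)", b = 0, se = 1),
            var_intercept = 1, var_residual = 1,
            fitted_fixed = rep(0, 100), converged = TRUE)
  class(f) <- class(n) <- "lmm_fit"
  cmp <- compare_models(f, n)
  expect_equal(cmp$bf10, exp(2))
  expect_equal(cmp$chi2, 4)
  expect_equal(cmp$bf01 * cmp$bf10, 1)
})

test_that("BF10 and BF01 are reciprocal for fitted comparisons", {
  set.seed(103)
  for (b in c(0, 0.3, 0.8)) {
    d <- simulate_lmm_dataset(20, 20, 2, b = b)
    cmp <- compare_models(fit_random_intercept(y ~ group, d),
                          fit_random_intercept(y ~ 1, d))
    expect_equal(cmp$bf10 * cmp$bf01, 1, tolerance = 1e-12)
  }
})

test_that("published Bayes-factor pairs are internally reciprocal at 2 dp", {
  bf <- published_bayes_factors()
  num <- bf[bf$bf10_bound == "none", ]
  ok <- mapply(function(b10, b01) {
    round(1 / b10, 2) == b01 || round(1 / b01, 2) == b10
  }, num$bf10, num$bf01)
  expect_true(all(ok))
  # bounded rows are consistent as inequalities: BF10 > 500 -> BF01 < 0.01
  bd <- bf[bf$bf10_bound == "gt", ]
  expect_true(all(1 / bd$bf10 <= bd$bf01))
})

test_that("marginal f2 is zero for identical models and recovers its target", {
  set.seed(104)
  d <- simulate_lmm_dataset(30, 30, 2, b = 0.5)
  full <- fit_random_intercept(y ~ group, d)
  expect_equal(marginal_f2(full, full), 0)

  # null effect: f2 estimates concentrate near zero
  f2_null <- vapply(1:30, function(s) {
    d0 <- simulate_lmm_dataset(30, 30, 2, b = 0, seed = 2000 + s)
    marginal_f2(fit_random_intercept(y ~ group, d0),
                fit_random_intercept(y ~ 1, d0))
  }, numeric(1))
  expect_lt(mean(f2_null), 0.03)

  # calibrated generating process: mean estimated f2 near the target
  b <- calibrate_group_effect(0.15, c(37, 50))
  f2_cal <- vapply(1:200, function(s) {
    dc <- simulate_lmm_dataset(37, 50, 2, b, seed = 3000 + s)
    marginal_f2(fit_random_intercept(y ~ group, dc),
                fit_random_intercept(y ~ 1, dc))
  }, numeric(1))
  expect_lt(abs(mean(f2_cal) - 0.15), 0.03)
})

test_that("chi-square is invariant to outcome rescaling; b and SE scale", {
  set.seed(105)
  d <- simulate_lmm_dataset(25, 25, 2, b = 0.4)
  cmp1 <- compare_models(fit_random_intercept(y ~ group, d),
                         fit_random_intercept(y ~ 1, d))
  d2 <- d; d2$y <- d$y * 1000
  cmp2 <- compare_models(fit_random_intercept(y ~ group, d2),
                         fit_random_intercept(y ~ 1, d2))
  expect_equal(cmp1$chi2, cmp2$chi2, tolerance = 1e-6)
  expect_equal(cmp1$p, cmp2$p, tolerance = 1e-6)
  expect_equal(cmp1$bf10, cmp2$bf10, tolerance = 1e-4)
  expect_equal(cmp2$b / cmp1$b, 1000, tolerance = 1e-3)
  expect_equal(cmp2$se / cmp1$se, 1000, tolerance = 1e-3)
})

test_that("model comparison rejects mismatched data", {
  set.seed(106)
  d <- simulate_lmm_dataset(10, 10, 2, b = 0)
  full <- fit_random_intercept(y ~ group, d)
  null <- fit_random_intercept(y ~ 1, d[1:30, ])
  expect_error(compare_models(full, null), "different numbers")
})

test_that("Benjamini-Hochberg flags match the hand-evaluated step-up rule", {
  expect_true(bh_adjust(0.01, q = 0.05))
  # largest i with p_(i) <= i q / m is i = 5: all five rejected
  expect_true(all(bh_adjust(c(0.01, 0.02, 0.03, 0.04, 0.05), q = 0.05)))
  expect_false(any(bh_adjust(rep(1, 4), q = 0.05)))
  expect_equal(bh_adjust(numeric(0)), logical(0))
  # monotone: any rejected p implies all smaller p rejected
  set.seed(107)
  for (i in 1:20) {
    p <- sort(runif(12))
    fl <- bh_adjust(p, q = 0.05)
    if (any(fl)) expect_true(all(fl[seq_len(max(which(fl)))]))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("power approaches 1 for very large effects and alpha under the null", {
  big <- power_simulation(f2 = 1.5, n_groups = c(15, 15), n_sims = 100,
                          seed = 21)
  expect_gt(big$power, 0.99)
})
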