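test_that("Egger regression agrees with the metafor regtest oracle", {
  skip_if_not_installed("metafor")
  ds <- priming_studies()
  eff <- effect_table(ds)
  own <- egger_test(ds)
  oracle <- metafor::regtest(metafor::rma(eff$yi, eff$vi, method = "REML"),
                             model = "rma", predictor = "sei")
  expect_equal(own$slope_stat, as.numeric(oracle$zval), tolerance = 1e-4)
  expect_equal(own$intercept, as.numeric(coef(oracle$fit)[1]), tolerance = 1e-5)
  expect_equal(own$intercept_ci[1], oracle$fit$ci.lb[1], tolerance = 1e-4)
  expect_equal(own$intercept_ci[2], oracle$fit$ci.ub[1], tolerance = 1e-4)
})

test_that("PET and the Egger test share one fit", {
  ds <- priming_studies()
  a <- egger_test(ds)
  b <- pet(ds)
  expect_identical(c(a$intercept, a$slope), c(b$intercept, b$slope))
  expect_identical(a$intercept_ci, b$intercept_ci)
})

test_that("a perfectly symmetric funnel shows no asymmetry", {
  ds <- symmetric_funnel_dataset(center = 0.4)
  a <- egger_test(ds, small_sample = "none")
  expect_lt(abs(a$slope_stat), 0.8)
  p <- peese(ds, small_sample = "none")
  pooled <- fit_random_effects(ds, small_sample = "none")$mu_hat
  expect_lt(abs(p$intercept - pooled), 0.05)
})

test_that("identical precisions make asymmetry untestable", {
  ds <- dataset_from_dnn(c(0.5, 0.5, 0.5), c(30, 30, 30), c(30, 30, 30))
  expect_error(egger_test(ds), "untestable")
})

test_that("shifting every effect moves the intercept, not the z statistic", {
  # exact at fixed sampling variances: the regression residuals are
  # unchanged, so tau2, the slope and its z are identical and the intercept
  # absorbs the full shift
  set.seed(11)
  d <- rnorm(12, 0.4, 0.3)
  n <- sample(15:60, 12, replace = TRUE)
  vi <- effect_table(dataset_from_dnn(d, n, n), small_sample = "none")$vi
  X <- cbind(1, sqrt(vi))
  base <- primingmeta:::meta_fit(d, vi, X, estimator = "REML")
  shift <- primingmeta:::meta_fit(d + 0.3, vi, X, estimator = "REML")
  expect_equal(shift$b[1] - base$b[1], 0.3, tolerance = 1e-6)
  expect_equal(shift$b[2] / shift$se_b[2], base$b[2] / base$se_b[2],
               tolerance = 1e-6)
  # on the dataset surface (variances recomputed from the shifted d) the
  # identity is approximate
  base_ds <- egger_test(dataset_from_dnn(d, n, n), small_sample = "none")
  shift_ds <- egger_test(dataset_from_dnn(d + 0.3, n, n), small_sample = "none")
  expect_lt(abs(shift_ds$intercept - base_ds$intercept - 0.3), 0.1)
})

test_that("PET recovers the true effect in unbiased literatures", {
  set.seed(23)
  k <- 250
  theta <- 0.5
  n <- sample(packaged_n_pool(), k, replace = TRUE)
  d <- vapply(seq_len(k), function(i) {
    x1 <- rnorm(n[i], theta); x2 <- rnorm(n[i], 0)
    sp <- sqrt(((n[i] - 1) * var(x1) + (n[i] - 1) * var(x2)) / (2 * n[i] - 2))
    hedges_j(2 * n[i] - 2) * (mean(x1) - mean(x2)) / sp
  }, numeric(1))
  ds <- dataset_from_dnn(d, n, n)
  expect_lt(abs(pet(ds)$intercept - theta), 0.25)
  expect_lt(abs(peese(ds)$intercept - theta), 0.2)
})

test_that("moderator-adjusted asymmetry stays strong on the packaged data", {
  # published lower bound: smallest adjusted z = 3.89
  z <- egger_test(priming_studies(), moderator = "prime_modality")$slope_stat
  expect_gte(z, 3.89)
})

test_that("PET-PEESE switches by the significance of the PET intercept", {
  ds <- priming_studies()
  two <- pet_peese(ds, rule = "two_tailed")
  expect_equal(two$selected, "peese")
  expect_equal(two$intercept, peese(ds)$intercept)
  one <- pet_peese(ds, rule = "one_tailed")  # PET intercept is negative
  expect_equal(one$selected, "pet")
  expect_equal(one$intercept, pet(ds)$intercept)
  # symmetric funnel: PET CI spans zero, both rules keep PET
  sym <- symmetric_funnel_dataset(center = 0.2)
  for (rule in c("two_tailed", "one_tailed")) {
    pp <- pet_peese(sym, rule = rule, small_sample = "none")
    expect_equal(pp$selected, "pet")
  }
})

test_that("funnel export has one point per study and a 1.96 se contour", {
  ds <- priming_studies()
  fd <- funnel_data(ds)
  expect_equal(nrow(fd$points), 13)
  expect_equal(fd$points$d, ds$records$d)
  expect_equal(fd$contour$upper, 1.96 * fd$contour$se, tolerance = 1e-3)
  expect_equal(fd$contour$lower, -fd$contour$upper)
})
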