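test_that("REML fit agrees with the metafor oracle on the packaged data", {
  skip_if_not_installed("metafor")
  ds <- priming_studies()
  eff <- effect_table(ds)
  fit <- fit_random_effects(ds)
  oracle <- metafor::rma(eff$yi, eff$vi, method = "REML")
  expect_equal(fit$mu_hat, as.numeric(oracle$b), tolerance = 1e-5)
  expect_equal(fit$tau2, oracle$tau2, tolerance = 1e-4)
  expect_equal(fit$se_mu, oracle$se, tolerance = 1e-5)
  expect_equal(fit$Q, oracle$QE, tolerance = 1e-8)
  expect_equal(fit$I2, oracle$I2, tolerance = 1e-3)
})

test_that("REML fit agrees with metafor across random datasets", {
  skip_if_not_installed("metafor")
  set.seed(42)
  for (i in 1:5) {
    k <- sample(5:25, 1)
    d <- rnorm(k, 0.4, 0.5)
    n <- sample(10:80, k, replace = TRUE)
    ds <- dataset_from_dnn(d, n, n)
    eff <- effect_table(ds)
    fit <- fit_random_effects(ds)
    oracle <- metafor::rma(eff$yi, eff$vi, method = "REML")
    expect_equal(fit$mu_hat, as.numeric(oracle$b), tolerance = 1e-4)
    expect_equal(fit$tau2, oracle$tau2, tolerance = 1e-4)
  }
})

test_that("degenerate and equal-precision cases reduce to closed forms", {
  # two identical records: no between-study variation
  ds <- dataset_from_dnn(c(0.5, 0.5), c(30, 30), c(30, 30),
                         ids = c("a", "b"))
  fit <- fit_random_effects(ds)
  eff <- effect_table(ds)
  expect_equal(fit$tau2, 0, tolerance = 1e-8)
  expect_equal(fit$mu_hat, eff$yi[1], tolerance = 1e-8)
  # equal vi and tau2 = 0 (FE): pooled mean is the unweighted average
  d <- c(0.41, 0.38, 0.44, 0.40)
  ds2 <- dataset_from_dnn(d, rep(40, 4), rep(40, 4))
  eff2 <- effect_table(ds2)
  # make vi exactly equal by fitting on a constant-variance copy
  fit2 <- primingmeta:::fit_random_effects_yv(eff2$yi, rep(0.05, 4),
                                              estimator = "FE")
  expect_equal(fit2$mu_hat, mean(eff2$yi))
  expect_error(fit_random_effects(dataset_from_dnn(0.3, 20, 20)), "k >= 2")
})

test_that("heterogeneity statistics obey their identities", {
  ds <- priming_studies()
  fits <- lapply(c("REML", "DL", "ML", "FE"), function(est) {
    fit_random_effects(ds, estimator = est)
  })
  Qs <- vapply(fits, `[[`, numeric(1), "Q")
  expect_true(all(abs(Qs - Qs[1]) < 1e-12))  # Q uses FE weights throughout
  for (f in fits) {
    expect_equal(f$Q_p, pchisq(f$Q, f$Q_df, lower.tail = FALSE))
    expect_gte(f$I2, 0); expect_lte(f$I2, 100)
    expect_true(f$ci_low <= f$mu_hat && f$mu_hat <= f$ci_high)
  }
  expect_equal(fits[[4]]$I2, 0)  # FE: tau2 = 0 forces I2 = 0
  # DL and REML tau2 agree within 10% on the packaged data
  reml <- fits[[1]]$tau2; dl <- fits[[2]]$tau2
  expect_lt(abs(reml - dl) / reml, 0.10)
})

test_that("moderator meta-regression detects and ignores as appropriate", {
  ds <- priming_studies()
  mod <- fit_moderator(ds, "prime_modality")
  expect_equal(mod$QM_df, 1)
  expect_gt(mod$QM_p, 0.05)   # published upper-bound: largest Q(1) = 1.13
  expect_lt(mod$QM, 3.9)
  expect_error(fit_moderator(ds, "lag_class"), "fewer than 2 coded")
  one_level <- dataset_from_dnn(c(0.2, 0.4, 0.3), rep(30, 3), rep(30, 3),
                                modality = "visual")
  expect_error(fit_moderator(one_level, "prime_modality"),
               "single observed level")
  # two levels separated by d = 1 with tiny sampling variance: QM must fire
  set.seed(7)
  k <- 20
  d <- c(rnorm(k, 0, 0.02), rnorm(k, 1, 0.02))
  ds2 <- dataset_from_dnn(d, rep(1000, 2 * k), rep(1000, 2 * k),
                          modality = rep(c("visual", "linguistic"), each = k))
  mod2 <- fit_moderator(ds2, "prime_modality", small_sample = "none")
  expect_lt(mod2$QM_p, 0.001)
  expect_equal(nrow(mod2$level_estimates), 2)
})

test_that("forest rows carry per-study CIs plus the pooled row", {
  ds <- priming_studies()
  fit <- fit_random_effects(ds)
  fr <- forest_data(fit, ds)
  expect_equal(nrow(fr), 14)
  expect_equal(fr$study_id[14], "pooled")
  s1 <- fr[fr$study_id == "shantz_s1", ]
  expect_equal(s1$d, 0.95)
  expect_true(s1$ci_low < s1$d && s1$d < s1$ci_high)
  # a null effect has a CI symmetric about zero
  ds0 <- dataset_from_dnn(c(0, 0.4), c(25, 30), c(25, 30))
  fr0 <- forest_data(fit_random_effects(ds0), ds0)
  expect_equal(fr0$ci_low[1], -fr0$ci_high[1])
})
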