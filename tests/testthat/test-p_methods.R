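test_that("pp-values at delta = 0 reduce to rescaled one-tailed p-values", {
  ds <- priming_studies()
  pp <- pp_values(ds, delta = 0)                 # t machinery, crit 0.025
  eff <- effect_table(ds)
  idx <- match(names(pp), eff$study_id)
  expect_equal(unname(pp),
               pmin(eff$p_one[idx] / pt(qt(0.975, eff$df[idx]), eff$df[idx],
                                        lower.tail = FALSE), 1),
               tolerance = 1e-10)
  expect_true(all(pp > 0 & pp <= 1))
  expect_gte(length(pp), 6)
})

test_that("pp-values increase with the assumed effect", {
  # a larger assumed effect makes every observed t less surprising, pushing
  # the conditional exceedance probability toward 1
  ds <- priming_studies()
  grid <- seq(-0.5, 1.5, by = 0.25)
  pp_mat <- sapply(grid, function(delta) pp_values(ds, delta))
  for (r in seq_len(nrow(pp_mat))) {
    expect_true(all(diff(pp_mat[r, ]) > -1e-12))
  }
})

test_that("pp-values are uniform at the true effect", {
  set.seed(91)
  delta <- 0.5
  ds <- sample_significant_studies(400, delta, n_per_group = 30)
  pp <- pp_values(ds, delta)
  expect_equal(length(pp), 400)   # all sampled studies pass the gate
  expect_equal(mean(pp), 0.5, tolerance = 0.05)
  expect_gt(suppressWarnings(ks.test(pp, punif))$p.value, 0.01)
})

test_that("p-curve and p-uniform share the significant subset", {
  ds <- priming_studies()
  pc <- pcurve_estimate(ds)
  pu <- puniform_estimate(ds)
  expect_setequal(pc$included_ids, pu$included_ids)
  expect_equal(pc$n_significant, 10)
  fl <- significance_flags(ds)
  eff <- effect_table(ds)
  gate <- eff$study_id[eff$zi > qnorm(0.975) & eff$yi > 0]
  expect_setequal(pc$included_ids, gate)
})

test_that("p-curve recovers the generating effect from significant studies", {
  # generation gate matches the estimator's conditioning boundary
  # (one-tailed t at 0.05); a mismatched gate would bias the estimate
  set.seed(101)
  ds <- sample_significant_studies(200, 0.5, n_per_group = 30, gate = "t95")
  est <- pcurve_estimate(ds)
  expect_lt(abs(est$delta_hat - 0.5), 0.1)
  # single-study case is defined but warns
  ds1 <- sample_significant_studies(2, 0.8, n_per_group = 40)
  one <- dataset_from_dnn(c(ds1$records$d[1], 0.01), c(40, 40), c(40, 40))
  expect_warning(pcurve_estimate(one), "single significant")
})

test_that("p-uniform is unbiased under pure significance selection", {
  # literatures of only-significant studies at delta = 0: the conditional
  # estimator should center on zero
  set.seed(113)
  reps <- 40
  ests <- vapply(seq_len(reps), function(r) {
    ds <- sample_significant_studies(8, 0, n_per_group = 30)
    puniform_estimate(ds)$delta_hat
  }, numeric(1))
  mc_se <- sd(ests) / sqrt(reps)
  expect_lt(abs(mean(ests)), 3 * mc_se + 0.02)
})

test_that("estimation errors name the degenerate subset", {
  ds <- dataset_from_dnn(c(0.05, -0.1, 0.02), c(30, 30, 30), c(30, 30, 30))
  expect_error(pcurve_estimate(ds), "no significant positive studies")
  expect_error(puniform_estimate(ds), "no significant positive studies")
  expect_error(pp_values(ds, 0), "subset size 0")
})
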