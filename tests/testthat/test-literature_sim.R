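test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(mu_true = 0.3, tau = 0.2, k_published = 15,
                    bias_level = "medium", qrp_level = "high", seed = 77)
  a <- simulate_literature(cfg)
  b <- simulate_literature(cfg)
  expect_identical(a$dataset$records, b$dataset$records)
  expect_identical(a$audit, b$audit)
  expect_identical(a$n_attempted, b$n_attempted)
})

test_that("without selection every attempted study is published", {
  lit <- simulate_literature(sim_config(mu_true = 0.4, tau = 0.1,
                                        k_published = 40, seed = 5))
  expect_equal(lit$n_attempted, 40L)
  expect_equal(nrow(lit$audit), 40)
  expect_true(all(lit$audit$operators == ""))
})

test_that("unbiased simulation recovers the true mean effect", {
  lit <- simulate_literature(sim_config(mu_true = 0.5, tau = 0,
                                        k_published = 500, seed = 11))
  eff <- effect_table(lit$dataset)
  mc_se <- sd(eff$yi) / sqrt(500)
  expect_lt(abs(mean(eff$yi) - 0.5), 3 * mc_se)
  expect_equal(lit$latent, rep(0.5, 500))
})

test_that("strong selection at a null effect publishes inflated positives", {
  lit <- simulate_literature(sim_config(mu_true = 0, tau = 0,
                                        k_published = 40,
                                        bias_level = "strong", seed = 13))
  eff <- effect_table(lit$dataset)
  expect_gt(mean(eff$yi), 0)
  # every survivor is either significant-positive or won the 5% lottery;
  # with the audit we can check the rule directly
  expect_true(all(lit$audit$significant |
                    lit$audit$study_id %in% lit$dataset$records$study_id))
  expect_gt(lit$n_attempted, 40)
})

test_that("published mean effect rises with the bias level", {
  means <- vapply(c("none", "medium", "strong"), function(b) {
    m <- vapply(1:25, function(r) {
      lit <- simulate_literature(sim_config(mu_true = 0, tau = 0.2,
                                            k_published = 10,
                                            bias_level = b,
                                            seed = 900 + r))
      mean(effect_table(lit$dataset)$yi)
    }, numeric(1))
    mean(m)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("REML recovers mu and tau from unbiased literatures", {
  set.seed(29)
  reps <- 40
  mus <- numeric(reps); taus <- numeric(reps)
  for (r in seq_len(reps)) {
    lit <- simulate_literature(sim_config(mu_true = 0.3, tau = 0.3,
                                          k_published = 200,
                                          seed = 3000 + r))
    fit <- fit_random_effects(lit$dataset)
    mus[r] <- fit$mu_hat; taus[r] <- sqrt(fit$tau2)
  }
  expect_lt(abs(mean(mus) - 0.3), 2 * sd(mus) / sqrt(reps) + 0.01)
  expect_lt(abs(mean(taus) - 0.3), 2 * sd(taus) / sqrt(reps) + 0.02)
})

test_that("QRP operators only fire on nonsignificant results", {
  lit <- simulate_literature(sim_config(mu_true = 0, tau = 0,
                                        k_published = 30,
                                        qrp_level = "high", seed = 41))
  aud <- lit$audit
  # optional stopping leaves its trace in enlarged samples
  stopped <- grepl("stop", aud$operators)
  expect_true(any(stopped))
  expect_true(all(aud$n_treatment[stopped] >= aud$n_initial[stopped]))
  expect_true(any(grepl("dv_switch", aud$operators)))
})

test_that("false-positive grid calibrates and inflates as expected", {
  # nominal calibration: unbiased conditions, naive random effects only
  reg <- estimator_registry()
  fpr0 <- fpr_grid(conditions = list(sim_config(mu_true = 0, tau = 0,
                                                k_published = 10)),
                   methods = reg["random_effects"], reps = 200, seed = 2)
  expect_lt(abs(fpr0$rates[["random_effects"]] - 5),
            3 * fpr0$mc_se_pct[["random_effects"]] + 2)
  # bias + QRPs at a null effect: naive RE false-positive rate blows up
  fpr1 <- fpr_grid(conditions = list(sim_config(mu_true = 0, tau = 0.4,
                                                k_published = 10,
                                                bias_level = "medium",
                                                qrp_level = "high")),
                   methods = reg["random_effects"], reps = 150, seed = 3)
  expect_gt(fpr1$rates[["random_effects"]], 20)
  # determinism of the grid
  fpr0b <- fpr_grid(conditions = list(sim_config(mu_true = 0, tau = 0,
                                                 k_published = 10)),
                    methods = reg["random_effects"], reps = 200, seed = 2)
  expect_identical(fpr0$rates, fpr0b$rates)
  expect_error(fpr_grid(list(sim_config(mu_true = 0.2)), reps = 100),
               "mu_true = 0")
  expect_error(fpr_grid(list(sim_config()), reps = 50), "reps")
})
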