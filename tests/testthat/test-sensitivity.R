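test_that("packaged worst-case FPR table holds the published percentages", {
  fpr <- packaged_fpr_table()
  expect_equal(fpr$rates[["p_curve"]], 88)
  expect_equal(fpr$rates[["3PSM"]], 14)
  expect_equal(fpr$provenance, "packaged_paper_values")
  expect_true(all(fpr$rates >= 0 & fpr$rates <= 100))
  expect_equal(length(fpr$rates), 8)
})

test_that("admissibility gate filters strictly and orders by rate", {
  fpr <- packaged_fpr_table()
  expect_equal(admissible_methods(fpr, 20), c("3PSM", "PET"))
  expect_equal(admissible_methods(fpr, 15), "3PSM")
  expect_setequal(admissible_methods(fpr, 100), names(fpr$rates))
  expect_message(out <- admissible_methods(fpr, 10), "no method")
  expect_length(out, 0)
  # monotone: widening the threshold can only add methods
  thresholds <- c(12, 15, 17, 20, 25, 40, 64, 90)
  sets <- lapply(thresholds, function(t) {
    suppressMessages(admissible_methods(fpr, t))
  })
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  }
})

test_that("full analysis reproduces module output slot for slot", {
  ds <- priming_studies()
  rep <- run_full_analysis(ds)
  expect_equal(rep$admissible_methods, c("3PSM", "PET"))
  re <- rep$methods$random_effects
  fit <- fit_random_effects(ds)
  expect_identical(re$estimate, fit$mu_hat)
  expect_identical(re$ci_low, fit$ci_low)
  expect_identical(rep$methods$PET$estimate, pet(ds)$intercept)
  expect_identical(rep$methods$`3PSM`$estimate, fit_3psm(ds)$mu)
  expect_identical(rep$methods$p_uniform$estimate,
                   puniform_estimate(ds)$delta_hat)
  expect_true(rep$methods$`3PSM`$admissible)
  expect_false(rep$methods$trim_and_fill$admissible)
  expect_equal(rep$k, 13)
  expect_setequal(names(rep$headline), c("PET", "3PSM"))
})

test_that("negating every effect mirrors the random-effects entry", {
  ds <- priming_studies()
  neg <- dataset_from_dnn(-ds$records$d, ds$records$n_treatment,
                          ds$records$n_control)
  a <- run_full_analysis(ds)$methods$random_effects
  # on the negated data every study is nonsignificant, so the 3PSM entry
  # legitimately warns about an unidentified omega
  b <- suppressWarnings(run_full_analysis(neg))$methods$random_effects
  expect_equal(b$estimate, -a$estimate, tolerance = 1e-8)
  expect_equal(b$ci_low, -a$ci_high, tolerance = 1e-8)
  expect_equal(b$ci_high, -a$ci_low, tolerance = 1e-8)
})

test_that("a k = 2 dataset degrades gracefully", {
  ds <- dataset_from_dnn(c(0.3, 0.5), c(30, 30), c(30, 30))
  rep <- suppressWarnings(run_full_analysis(ds))
  expect_true(is.finite(rep$methods$random_effects$estimate))
  expect_match(rep$methods$PET$error, "k >= 3")
  expect_match(rep$methods$trim_and_fill$error, "k >= 3")
})

test_that("the JSON report round-trips", {
  ds <- priming_studies()
  rep <- run_full_analysis(ds)
  path <- withr::local_tempfile(fileext = ".json")
  write_report(rep, path)
  back <- read_report(path)
  expect_equal(back$threshold_pct, rep$threshold_pct)
  expect_equal(back$admissible_methods, rep$admissible_methods)
  for (mn in names(rep$methods)) {
    expect_equal(back$methods[[mn]]$estimate, rep$methods[[mn]]$estimate,
                 tolerance = 1e-12)
    expect_equal(back$methods[[mn]]$admissible, rep$methods[[mn]]$admissible)
  }
})
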