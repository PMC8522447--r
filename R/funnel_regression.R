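egger_fit <- function(dataset, predictor = c("se", "variance"),
                      model = c("mixed_effects", "wls"),
                      moderator = NULL, small_sample = "printed_g") {
  predictor <- match.arg(predictor)
  model <- match.arg(model)
  eff <- effect_table(dataset, small_sample = small_sample)
  if (nrow(eff) < 3) stop("k >= 3 studies required for asymmetry regression", call. = FALSE)
  x <- if (predictor == "se") eff$sei else eff$vi
  if (stats::sd(x) < 1e-12) {
    stop("all studies share one precision; funnel asymmetry is untestable",
         call. = FALSE)
  }
  X <- cbind(intercept = 1, x = x)
  if (!is.null(moderator)) {
    lev <- factor(dataset$records[[moderator]])
    if (nlevels(lev) < 2) {
      stop("moderator '", moderator, "' has a single observed level", call. = FALSE)
    }
    X <- cbind(X, stats::model.matrix(~lev)[, -1, drop = FALSE])
  }
  if (model == "mixed_effects") {
    f <- meta_fit(eff$yi, eff$vi, X, estimator = "REML")
    crit <- stats::qnorm(0.975)
    stat_p <- function(est, se) 2 * stats::pnorm(-abs(est / se))
  } else {
    # classical WLS Egger: weights 1/vi, t-based inference
    fit <- stats::lm(eff$yi ~ X - 1, weights = 1 / eff$vi)
    sm <- summary(fit)
    f <- list(b = stats::coef(fit), se_b = sm$coefficients[, 2],
              tau2 = NA_real_, k = nrow(eff), p = ncol(X))
    crit <- stats::qt(0.975, nrow(eff) - ncol(X))
    stat_p <- function(est, se) {
      2 * stats::pt(-abs(est / se), nrow(eff) - ncol(X))
    }
  }
  list(b = unname(f$b), se_b = unname(f$se_b), crit = crit,
       tau2 = f$tau2, stat_p = stat_p, predictor = predictor, model = model,
       k = nrow(eff), eff = eff)
}

as_asymmetry_result <- function(f) {
  structure(list(
    intercept = f$b[1], intercept_se = f$se_b[1],
    intercept_ci = c(f$b[1] - f$crit * f$se_b[1],
                     f$b[1] + f$crit * f$se_b[1]),
    intercept_stat = f$b[1] / f$se_b[1],
    intercept_p = f$stat_p(f$b[1], f$se_b[1]),
    slope = f$b[2], slope_se = f$se_b[2],
    slope_stat = f$b[2] / f$se_b[2],
    slope_p = f$stat_p(f$b[2], f$se_b[2]),
    tau2 = f$tau2, predictor = f$predictor, model = f$model, k = f$k
  ), class = "asymmetry_result")
}

#' @export
print.asymmetry_result <- function(x, ...) {
  cat(sprintf("funnel asymmetry regression (%s, predictor = %s), k = %d\n",
              x$model, x$predictor, x$k))
  cat(sprintf("  intercept = %.4f, CI [%.4f, %.4f]\n",
              x$intercept, x$intercept_ci[1], x$intercept_ci[2]))
  cat(sprintf("  slope = %.4f, z = %.4f, p = %.3g\n",
              x$slope, x$slope_stat, x$slope_p))
  invisible(x)
}

#' Egger-type regression test for funnel-plot asymmetry
#'
#' Fits the mixed-effects meta-regression yi = b0 + b1 * sei with REML
#' between-study variance; the slope z statistic (b1 / SE referred to the
#' standard normal) tests the small-study effect. Optionally adjusts for one
#' moderator (dummy-coded) alongside the standard error.
#'
#' @param dataset a `study_dataset`
#' @param model `"mixed_effects"` (default) or `"wls"` (classical weighted
#'   least squares with t inference, for cross-checks)
#' @param moderator optional moderator column name to adjust for
#' @param small_sample effect-scale convention, see [effect_table()]
#' @return an `asymmetry_result` with `intercept`, `intercept_ci`, `slope`,
#'   `slope_stat`, `slope_p`, `predictor`, `model`
#' @export
egger_test <- function(dataset, model = "mixed_effects", moderator = NULL,
                       small_sample = "printed_g") {
  as_asymmetry_result(egger_fit(dataset, predictor = "se", model = model,
                                moderator = moderator,
                                small_sample = small_sample))
}

#' PET: precision-effect test corrected estimate
#'
#' The intercept of the Egger regression (effect at SE -> 0) with its
#' confidence interval, returned as the bias-corrected estimate. Shares one
#' fit with [egger_test()]: coefficients are identical.
#'
#' @inheritParams egger_test
#' @return an `asymmetry_result`; `intercept` is the PET estimate
#' @export
pet <- function(dataset, model = "mixed_effects", small_sample = "printed_g") {
  egger_test(dataset, model = model, small_sample = small_sample)
}

#' PEESE: precision-effect estimate with standard errors
#'
#' Same regression with the sampling variance vi (rather than sei) as
#' predictor; the intercept is the PEESE corrected estimate.
#'
#' @inheritParams egger_test
#' @return an `asymmetry_result`; `intercept` is the PEESE estimate
#' @export
peese <- function(dataset, model = "mixed_effects", small_sample = "printed_g") {
  as_asymmetry_result(egger_fit(dataset, predictor = "variance", model = model,
                                small_sample = small_sample))
}

#' Conditional PET-PEESE estimator
#'
#' Under the default `two_tailed` rule, returns the PEESE result when the PET
#' intercept differs from zero at two-tailed alpha = 0.05, else the PET
#' result. Under `one_tailed`, switches to PEESE only when the PET intercept
#' is significantly greater than zero (one-tailed 0.05).
#'
#' @inheritParams egger_test
#' @param rule `"two_tailed"` (default) or `"one_tailed"`
#' @return an `asymmetry_result` (the selected branch) with an added
#'   `selected` element, `"pet"` or `"peese"`
#' @export
pet_peese <- function(dataset, rule = c("two_tailed", "one_tailed"),
                      model = "mixed_effects", small_sample = "printed_g") {
  rule <- match.arg(rule)
  p <- pet(dataset, model = model, small_sample = small_sample)
  switch_to_peese <- if (rule == "two_tailed") {
    p$intercept_p < 0.05
  } else {
    p$intercept > 0 && p$intercept_p / 2 < 0.05
  }
  out <- if (switch_to_peese) {
    peese(dataset, model = model, small_sample = small_sample)
  } else {
    p
  }
  out$selected <- if (switch_to_peese) "peese" else "pet"
  out$rule <- rule
  out
}

#' Funnel-plot data
#'
#' One point per study — effect and standard error on the printed
#' (small-sample-corrected) scale, plus the inverse standard error — and the
#' two-tailed 0.05 significance contour |d| = 1.96 se sampled over the
#' observed precision range.
#'
#' @param dataset a `study_dataset`
#' @param n_contour number of contour sample points (default 100)
#' @param small_sample effect-scale convention, see [effect_table()]
#' @return list with `points` (data.frame `study_id`, `d`, `se`,
#'   `inverse_se`) and `contour` (data.frame `se`, `lower`, `upper`)
#' @export
funnel_data <- function(dataset, n_contour = 100, small_sample = "printed_g") {
  eff <- effect_table(dataset, small_sample = small_sample)
  se <- eff$J * eff$sei
  points <- data.frame(study_id = eff$study_id, d = dataset$records$d,
                       se = se, inverse_se = 1 / se, stringsAsFactors = FALSE)
  se_grid <- seq(0, max(se) * 1.05, length.out = n_contour)
  z <- stats::qnorm(0.975)
  list(points = points,
       contour = data.frame(se = se_grid, lower = -z * se_grid,
                            upper = z * se_grid))
}
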