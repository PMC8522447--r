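# Core REML machinery shared by the pooled fit, meta-regression moderator
# tests and the Egger-type asymmetry regressions. Fisher scoring on tau2 with
# projection to tau2 >= 0; convergence when successive tau2 differ by < tol.
reml_tau2 <- function(yi, vi, X, tol = 1e-10, maxit = 100) {
  k <- length(yi)
  p <- ncol(X)
  tau2 <- max(0, stats::var(yi) - mean(vi))
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    W <- 1 / (vi + tau2)
    WX <- X * W
    XtWXi <- solve(crossprod(X, WX))
    P <- diag(W, k) - WX %*% XtWXi %*% t(WX)
    score <- -0.5 * sum(diag(P)) + 0.5 * sum((P %*% yi)^2)
    info <- 0.5 * sum(P * P)
    tau2_new <- max(0, tau2 + score / info)
    trace <- c(trace, tau2_new)
    if (abs(tau2_new - tau2) < tol) {
      tau2 <- tau2_new
      converged <- TRUE
      break
    }
    tau2 <- tau2_new
  }
  if (!converged) {
    stop(structure(class = c("reml_convergence_error", "error", "condition"),
                   list(message = sprintf(
                     "REML did not converge in %d iterations (last tau2: %s)",
                     maxit, paste(utils::tail(format(trace, digits = 10), 5),
                                  collapse = ", ")),
                     call = NULL, trace = trace)))
  }
  tau2
}

ml_tau2 <- function(yi, vi, X, tol = 1e-10, maxit = 200) {
  # profile ML over tau2 (used for the 3PSM likelihood-ratio baseline)
  nll <- function(t2) {
    W <- 1 / (vi + t2)
    WX <- X * W
    b <- solve(crossprod(X, WX), crossprod(WX, yi))
    r <- yi - X %*% b
    0.5 * sum(log(vi + t2)) + 0.5 * sum(W * r^2)
  }
  stats::optimize(nll, c(0, max(vi) * 10 + stats::var(yi) * 10),
                  tol = tol)$minimum
}

# Weighted least squares at a given tau2: coefficients, covariance, residual Q
wls_at_tau2 <- function(yi, vi, X, tau2) {
  W <- 1 / (vi + tau2)
  WX <- X * W
  XtWXi <- solve(crossprod(X, WX))
  b <- XtWXi %*% crossprod(WX, yi)
  list(b = drop(b), vb = XtWXi, w = W)
}

# Cochran's Q: residual weighted SS at tau2 = 0 (fixed-effect weights);
# identical across tau2 estimator choices.
cochran_q <- function(yi, vi, X) {
  fit <- wls_at_tau2(yi, vi, X, 0)
  sum((yi - X %*% fit$b)^2 / vi)
}

meta_fit <- function(yi, vi, X, estimator = "REML", ci_level = 0.95,
                     knapp_hartung = FALSE) {
  k <- length(yi)
  p <- ncol(X)
  tau2 <- switch(estimator,
    FE = 0,
    REML = reml_tau2(yi, vi, X),
    ML = ml_tau2(yi, vi, X),
    DL = {
      if (p > 1) stop("DL estimator implemented for intercept-only models", call. = FALSE)
      w <- 1 / vi
      Q <- cochran_q(yi, vi, X)
      C <- sum(w) - sum(w^2) / sum(w)
      max(0, (Q - (k - 1)) / C)
    },
    stop("unknown estimator: ", estimator, call. = FALSE)
  )
  fit <- wls_at_tau2(yi, vi, X, tau2)
  se_b <- sqrt(diag(fit$vb))
  if (knapp_hartung) {
    resid <- yi - X %*% fit$b
    s2 <- sum(fit$w * resid^2) / (k - p)
    se_b <- se_b * sqrt(max(s2, 0))
    crit <- stats::qt(1 - (1 - ci_level) / 2, k - p)
  } else {
    crit <- stats::qnorm(1 - (1 - ci_level) / 2)
  }
  Q <- cochran_q(yi, vi, X)
  list(b = fit$b, vb = fit$vb, se_b = se_b, crit = crit, tau2 = tau2,
       Q = Q, Q_df = k - p, w = fit$w, k = k, p = p,
       knapp_hartung = knapp_hartung)
}

#' Random-effects meta-analysis of a study dataset
#'
#' Fits the random-effects model yi ~ N(mu, tau2 + vi) by inverse-variance
#' weighting, with tau2 estimated by REML (default; Fisher scoring, converged
#' when successive tau2 differ by < 1e-10), DerSimonian-Laird, ML, or fixed at
#' zero (`FE`). Wald z confidence intervals by default; the Knapp-Hartung
#' t-based adjustment is available behind a flag.
#'
#' Heterogeneity: Cochran's Q with fixed-effect weights (identical across
#' estimator choices), and I2 on the tau2-based definition
#' I2 = 100 tau2 / (tau2 + s2) with the typical within-study variance
#' s2 = (k-1) sum(wi) / ((sum wi)^2 - sum(wi^2)), wi = 1/vi.
#'
#' @param dataset a `study_dataset`
#' @param estimator `"REML"` (default), `"DL"`, `"ML"` or `"FE"`
#' @param ci_level confidence level, default 0.95
#' @param knapp_hartung use the Knapp-Hartung adjustment (default FALSE)
#' @param small_sample effect-scale convention, see [effect_table()]
#' @return a `meta_result` list: `k`, `mu_hat`, `se_mu`, `ci_low`, `ci_high`,
#'   `tau2`, `I2`, `Q`, `Q_df`, `Q_p`, `weights` (normalized to percent),
#'   `estimator`, `effects` (the [effect_table()] used)
#' @export
fit_random_effects <- function(dataset, estimator = c("REML", "DL", "ML", "FE"),
                               ci_level = 0.95, knapp_hartung = FALSE,
                               small_sample = "printed_g") {
  estimator <- match.arg(estimator)
  eff <- effect_table(dataset, small_sample = small_sample)
  fit_random_effects_yv(eff$yi, eff$vi, estimator = estimator,
                        ci_level = ci_level, knapp_hartung = knapp_hartung,
                        effects = eff)
}

# Same fit from bare (yi, vi) vectors; used on filled/simulated sets.
fit_random_effects_yv <- function(yi, vi, estimator = "REML", ci_level = 0.95,
                                  knapp_hartung = FALSE, effects = NULL) {
  if (length(yi) < 2) stop("k >= 2 studies required", call. = FALSE)
  X <- matrix(1, length(yi), 1)
  f <- meta_fit(yi, vi, X, estimator = estimator, ci_level = ci_level,
                knapp_hartung = knapp_hartung)
  w_fe <- 1 / vi
  s2 <- (f$k - 1) * sum(w_fe) / (sum(w_fe)^2 - sum(w_fe^2))
  I2 <- 100 * f$tau2 / (f$tau2 + s2)
  structure(list(
    k = f$k, mu_hat = f$b[1], se_mu = f$se_b[1],
    ci_low = f$b[1] - f$crit * f$se_b[1],
    ci_high = f$b[1] + f$crit * f$se_b[1],
    tau2 = f$tau2, I2 = I2, Q = f$Q, Q_df = f$Q_df,
    Q_p = stats::pchisq(f$Q, f$Q_df, lower.tail = FALSE),
    weights = 100 * f$w / sum(f$w),
    estimator = estimator, ci_level = ci_level, effects = effects
  ), class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("random-effects meta-analysis (%s), k = %d\n", x$estimator, x$k))
  cat(sprintf("  pooled d = %.4f, %g%% CI [%.4f, %.4f]\n",
              x$mu_hat, 100 * x$ci_level, x$ci_low, x$ci_high))
  cat(sprintf("  tau2 = %.4f, I2 = %.1f%%, Q(%d) = %.4f, p = %.4f\n",
              x$tau2, x$I2, x$Q_df, x$Q, x$Q_p))
  invisible(x)
}

#' Single-moderator mixed-effects meta-regression
#'
#' Dummy-codes one moderator column (levels coded `"unknown"` are dropped),
#' fits the mixed-effects meta-regression with REML tau2, and reports the Wald
#' omnibus chi-square test QM of the moderator coefficients on
#' (number of levels - 1) df, plus per-level pooled estimates.
#'
#' @param dataset a `study_dataset`
#' @param moderator one of `"prime_modality"`, `"prime_specificity"`,
#'   `"lag_class"`
#' @param small_sample effect-scale convention, see [effect_table()]
#' @return a `moderator_result` list: `QM`, `QM_df`, `QM_p`, `tau2`,
#'   `level_estimates` (data.frame level/estimate/se), `moderator`
#' @export
fit_moderator <- function(dataset, moderator, small_sample = "printed_g") {
  if (!moderator %in% c("prime_modality", "prime_specificity", "lag_class")) {
    stop("unknown moderator column: ", moderator, call. = FALSE)
  }
  eff <- effect_table(dataset, small_sample = small_sample)
  lev_raw <- dataset$records[[moderator]]
  keep <- lev_raw != "unknown"
  if (sum(keep) < 2) stop("moderator has fewer than 2 coded studies", call. = FALSE)
  lev <- factor(lev_raw[keep])
  if (nlevels(lev) < 2) {
    stop("moderator '", moderator, "' has a single observed level", call. = FALSE)
  }
  yi <- eff$yi[keep]; vi <- eff$vi[keep]
  X <- stats::model.matrix(~lev)
  f <- meta_fit(yi, vi, X, estimator = "REML")
  idx <- 2:ncol(X)
  bm <- f$b[idx]
  QM <- drop(t(bm) %*% solve(f$vb[idx, idx, drop = FALSE]) %*% bm)
  # per-level pooled estimates from the cell-means parameterization
  Xc <- stats::model.matrix(~lev - 1)
  fc <- wls_at_tau2(yi, vi, Xc, f$tau2)
  structure(list(
    QM = QM, QM_df = length(idx),
    QM_p = stats::pchisq(QM, length(idx), lower.tail = FALSE),
    tau2 = f$tau2,
    level_estimates = data.frame(level = levels(lev), estimate = fc$b,
                                 se = sqrt(diag(fc$vb)),
                                 stringsAsFactors = FALSE),
    moderator = moderator
  ), class = "moderator_result")
}

#' Forest-plot data
#'
#' Per-study rows with 95% CIs (d +/- 1.96 se) followed by the pooled row.
#' With `scale = "printed"` (default) rows are on the published
#' small-sample-corrected scale — the effect as printed, with standard error
#' J * se(yi); `scale = "analysis"` leaves everything on the uncorrected
#' Cohen's d scale of the fit.
#'
#' @param result a `meta_result` fitted by [fit_random_effects()] on `dataset`
#' @param dataset the `study_dataset` the result was fitted on
#' @param scale `"printed"` or `"analysis"`
#' @return data.frame with `study_id`, `d`, `ci_low`, `ci_high`, `weight_pct`;
#'   the last row (`study_id = "pooled"`) is the meta-analytic estimate
#' @export
forest_data <- function(result, dataset, scale = c("printed", "analysis")) {
  scale <- match.arg(scale)
  eff <- result$effects
  if (is.null(eff)) eff <- effect_table(dataset)
  z <- stats::qnorm(0.975)
  if (scale == "printed") {
    d <- dataset$records$d
    se <- eff$J * eff$sei
  } else {
    d <- eff$yi
    se <- eff$sei
  }
  rows <- data.frame(study_id = eff$study_id, d = d,
                     ci_low = d - z * se, ci_high = d + z * se,
                     weight_pct = result$weights, stringsAsFactors = FALSE)
  pooled <- data.frame(study_id = "pooled", d = result$mu_hat,
                       ci_low = result$ci_low, ci_high = result$ci_high,
                       weight_pct = 100, stringsAsFactors = FALSE)
  rbind(rows, pooled)
}
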