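#' Cohen's d from two-group summary statistics
#'
#' d = (mean1 - mean2) / s_pooled with
#' s_pooled = sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2)).
#'
#' @param mean1,mean2 group means (group 1 = treatment)
#' @param sd1,sd2 group standard deviations, > 0
#' @param n1,n2 per-group sample sizes, > 1 (fractional allowed)
#' @return an `effect_estimate` list: `d`, `variance`, `se`, `df`, `t_stat`,
#'   `p_one`, `p_two` (variance and test statistics as in [attach_variance()])
#' @export
d_from_groups <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (sd1 <= 0 || sd2 <= 0) stop("group standard deviations must be positive", call. = FALSE)
  if (n1 <= 1 || n2 <= 1) stop("per-group n must exceed 1", call. = FALSE)
  s_pooled <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  attach_variance((mean1 - mean2) / s_pooled, n1, n2)
}

#' Sampling variance and test statistics for a standardized mean difference
#'
#' Uses the standard large-sample variance of Cohen's d,
#' v = (n1+n2)/(n1 n2) + d^2 / (2 (n1+n2)), and the two-sample t statistic on
#' the summary scale, t = d * sqrt(n1 n2 / (n1+n2)), referred to the central t
#' distribution with df = n1 + n2 - 2 (fractional df pass straight through).
#'
#' @param d standardized mean difference
#' @param n1,n2 per-group sample sizes (> 0, fractional allowed)
#' @return an `effect_estimate` list with `d`, `variance`, `se`, `df`,
#'   `t_stat`, `p_one` (upper tail), `p_two`
#' @export
attach_variance <- function(d, n1, n2) {
  if (n1 <= 0 || n2 <= 0) stop("per-group n must be positive", call. = FALSE)
  df <- n1 + n2 - 2
  if (df <= 0) stop("n1 + n2 must exceed 2 (df <= 0)", call. = FALSE)
  variance <- (n1 + n2) / (n1 * n2) + d^2 / (2 * (n1 + n2))
  t_stat <- d * sqrt(n1 * n2 / (n1 + n2))
  p_one <- stats::pt(t_stat, df, lower.tail = FALSE)
  structure(list(d = d, variance = variance, se = sqrt(variance), df = df,
                 t_stat = t_stat, p_one = p_one,
                 p_two = 2 * min(p_one, 1 - p_one)),
            class = "effect_estimate")
}

#' Hedges' small-sample correction factor
#'
#' J = 1 - 3/(4 df - 1), the multiplier converting Cohen's d to Hedges' g.
#'
#' @param df degrees of freedom n1 + n2 - 2 (fractional allowed)
#' @return correction factor in (0, 1)
#' @export
hedges_j <- function(df) 1 - 3 / (4 * df - 1)

#' Per-study effects on the analysis scale
#'
#' Expands a `study_dataset` into the per-study quantities every estimator in
#' the package consumes: the analysis-scale effect `yi`, its sampling variance
#' `vi` and standard error `sei`, the t statistic, degrees of freedom, and
#' one- and two-tailed p-values (central t), plus the normal-scale
#' `zi = yi / sei` used by selection-keyed methods.
#'
#' Published study tables in this literature print the small-sample-corrected
#' effect (Hedges' g, commonly still labelled d). The default
#' `small_sample = "printed_g"` therefore back-transforms to the uncorrected
#' Cohen's d scale, yi = d_printed / J with J = 1 - 3/(4 df - 1), before
#' attaching the large-sample variance; this is the convention under which the
#' package reproduces the published pooled results for the packaged dataset.
#' Use `small_sample = "none"` to take the d column at face value.
#'
#' @param dataset a `study_dataset`
#' @param small_sample `"printed_g"` (default) or `"none"`
#' @return data.frame with one row per study: `study_id`, `yi`, `vi`, `sei`,
#'   `J`, `df`, `t_stat`, `zi`, `p_one`, `p_two`, `n_treatment`, `n_control`
#' @export
effect_table <- function(dataset, small_sample = c("printed_g", "none")) {
  small_sample <- match.arg(small_sample)
  r <- dataset$records
  df <- r$n_treatment + r$n_control - 2
  J <- hedges_j(df)
  yi <- if (small_sample == "printed_g") r$d / J else r$d
  m <- r$n_treatment + r$n_control
  vi <- m / (r$n_treatment * r$n_control) + yi^2 / (2 * m)
  t_stat <- yi * sqrt(r$n_treatment * r$n_control / m)
  p_one <- stats::pt(t_stat, df, lower.tail = FALSE)
  data.frame(study_id = r$study_id, yi = yi, vi = vi, sei = sqrt(vi), J = J,
             df = df, t_stat = t_stat, zi = yi / sqrt(vi), p_one = p_one,
             p_two = 2 * pmin(p_one, 1 - p_one),
             n_treatment = r$n_treatment, n_control = r$n_control,
             stringsAsFactors = FALSE)
}

#' Per-study significance flags
#'
#' Flags each study as significant at `alpha` with the stated sidedness
#' (one-sided tests are in the positive direction) and records the direction
#' of the effect. Tests use the central t distribution with df = n1 + n2 - 2.
#'
#' @param dataset a `study_dataset`
#' @param alpha significance level in (0, 1)
#' @param sidedness `"two"` (default) or `"one"`
#' @param small_sample passed to [effect_table()]
#' @return data.frame with `study_id`, `significant`, `positive`
#' @export
significance_flags <- function(dataset, alpha = 0.05,
                               sidedness = c("two", "one"),
                               small_sample = "printed_g") {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  sidedness <- match.arg(sidedness)
  eff <- effect_table(dataset, small_sample = small_sample)
  sig <- if (sidedness == "two") eff$p_two < alpha else eff$p_one < alpha
  data.frame(study_id = eff$study_id, significant = sig,
             positive = eff$yi > 0, stringsAsFactors = FALSE)
}
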