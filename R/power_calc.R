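#' Power of the two-sample t-test for a standardized mean difference
#'
#' Exact noncentral-t power with equal per-group n: noncentrality
#' ncp = d sqrt(n/2), df = 2n - 2, and for a one-sided test
#' power = P(T_ncp > t_{1-alpha, df}); the two-sided test adds the lower
#' rejection tail.
#'
#' @param d assumed population standardized mean difference
#' @param n_per_group per-group sample size (> 1; fractional allowed)
#' @param alpha significance level in (0, 0.5]
#' @param sidedness `"one"` (default) or `"two"`
#' @return rejection probability
#' @export
power_two_group <- function(d, n_per_group, alpha = 0.05,
                            sidedness = c("one", "two")) {
  sidedness <- match.arg(sidedness)
  if (alpha <= 0 || alpha > 0.5) stop("alpha must be in (0, 0.5]", call. = FALSE)
  if (n_per_group <= 1) stop("n_per_group must exceed 1", call. = FALSE)
  df <- 2 * n_per_group - 2
  ncp <- d * sqrt(n_per_group / 2)
  if (sidedness == "one") {
    crit <- stats::qt(1 - alpha, df)
    stats::pt(crit, df, ncp, lower.tail = FALSE)
  } else {
    crit <- stats::qt(1 - alpha / 2, df)
    stats::pt(crit, df, ncp, lower.tail = FALSE) +
      stats::pt(-crit, df, ncp)
  }
}

#' Detectable effect size for a target power
#'
#' Inverts [power_two_group()] over d by bisection on [0, 5] to tolerance
#' 1e-6.
#'
#' @param power_target desired power, in (alpha, 1)
#' @param n_per_group per-group sample size
#' @param alpha significance level
#' @param sidedness `"one"` (default) or `"two"`
#' @return the population d at which the test attains `power_target`
#' @export
required_d <- function(power_target, n_per_group, alpha = 0.05,
                       sidedness = c("one", "two")) {
  sidedness <- match.arg(sidedness)
  if (power_target <= alpha || power_target >= 1) {
    stop("power_target must lie in (alpha, 1)", call. = FALSE)
  }
  f <- function(d) {
    power_two_group(d, n_per_group, alpha, sidedness) - power_target
  }
  lo <- 0; hi <- 5
  if (f(hi) < 0) stop("power target unreachable for d <= 5", call. = FALSE)
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
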