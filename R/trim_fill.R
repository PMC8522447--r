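#' Duval-Tweedie trim-and-fill
#'
#' Estimates the number k0 of studies suppressed on one side of the funnel,
#' imputes their mirror images, and refits the random-effects model.
#'
#' Iterative algorithm with fixed-effect centering: (1) estimate the center by
#' an inverse-variance fixed-effect fit of the trimmed set; (2) rank the
#' absolute deviations of all studies about that center (average ranks on
#' ties) and compute k0 from the chosen estimator — `L0` from the rank-sum of
#' the deviations on the asymmetric side, `L0 = (4 T - n(n+1)) / (2n - 1)`
#' rounded to a non-negative integer, or `R0` from the length of the rightmost
#' run of same-side deviations; (3) trim the k0 most extreme studies on that
#' side and repeat until k0 is stable (at most 50 iterations); (4) fill mirror
#' images `y* = 2 center - y_donor` (donor's variance) and refit the full
#' REML random-effects model on observed + imputed.
#'
#' @param dataset a `study_dataset`
#' @param side `"left"` (default; missing studies assumed on the left),
#'   `"right"`, or `"auto"` (the side with the smaller deviation rank-sum)
#' @param estimator `"L0"` (default) or `"R0"`
#' @param small_sample effect-scale convention, see [effect_table()]
#' @return a `trim_fill_result` list: `k0`, `side`, `estimator`, `adjusted`
#'   (a `meta_result` on observed + imputed), `imputed_effects` (data.frame
#'   `yi`, `vi`), `unadjusted` (`meta_result` on the observed set),
#'   `iterations`
#' @export
trim_and_fill <- function(dataset, side = c("left", "right", "auto"),
                          estimator = c("L0", "R0"),
                          small_sample = "printed_g") {
  side <- match.arg(side)
  estimator <- match.arg(estimator)
  eff <- effect_table(dataset, small_sample = small_sample)
  if (nrow(eff) < 3) stop("k >= 3 studies required for trim-and-fill", call. = FALSE)
  yi <- eff$yi; vi <- eff$vi

  if (side == "auto") {
    w <- 1 / vi
    center <- sum(w * yi) / sum(w)
    rk <- rank(abs(yi - center))
    side <- if (sum(rk[yi - center < 0]) < sum(rk[yi - center > 0])) "left" else "right"
  }
  # work on a flipped scale where the missing side is the left, so the
  # observed excess (donor studies) is on the right
  flip <- if (side == "left") 1 else -1
  y <- flip * yi

  k0 <- 0L
  iterations <- 0L
  repeat {
    iterations <- iterations + 1L
    keep <- seq_along(y)
    if (k0 > 0) {
      drop_idx <- order(y, decreasing = TRUE)[seq_len(min(k0, length(y) - 2))]
      keep <- setdiff(keep, drop_idx)
    }
    w <- 1 / vi[keep]
    center <- sum(w * y[keep]) / sum(w)
    e <- y - center
    rk <- rank(abs(e))
    n <- length(y)
    k0_new <- if (estimator == "L0") {
      T_pos <- sum(rk[e > 0])
      max(0, round((4 * T_pos - n * (n + 1)) / (2 * n - 1)))
    } else {
      ord <- order(rk, decreasing = TRUE)
      run <- 0L
      for (j in ord) {
        if (e[j] > 0) run <- run + 1L else break
      }
      max(0, run - 1L)
    }
    k0_new <- as.integer(k0_new)
    if (k0_new == k0 || iterations >= 50) {
      if (iterations >= 50 && k0_new != k0) {
        warning("trim-and-fill k0 oscillated; returning last stable value",
                call. = FALSE)
        k0_new <- k0
      }
      k0 <- k0_new
      break
    }
    k0 <- k0_new
  }

  # final center from the trimmed set, then fill mirror images
  keep <- seq_along(y)
  if (k0 > 0) {
    drop_idx <- order(y, decreasing = TRUE)[seq_len(min(k0, length(y) - 2))]
    keep <- setdiff(keep, drop_idx)
  }
  w <- 1 / vi[keep]
  center <- sum(w * y[keep]) / sum(w)

  unadjusted <- fit_random_effects_yv(yi, vi, estimator = "REML")
  if (k0 > 0) {
    donors <- order(y, decreasing = TRUE)[seq_len(min(k0, length(y)))]
    y_fill <- flip * (2 * center - y[donors])
    v_fill <- vi[donors]
    adjusted <- fit_random_effects_yv(c(yi, y_fill), c(vi, v_fill),
                                      estimator = "REML")
    imputed <- data.frame(yi = y_fill, vi = v_fill)
  } else {
    adjusted <- unadjusted
    imputed <- data.frame(yi = numeric(0), vi = numeric(0))
  }
  structure(list(k0 = k0, side = side, estimator = estimator,
                 adjusted = adjusted, imputed_effects = imputed,
                 unadjusted = unadjusted, center = flip * center,
                 iterations = iterations),
            class = "trim_fill_result")
}

#' @export
print.trim_fill_result <- function(x, ...) {
  cat(sprintf("trim-and-fill (%s, side = %s): k0 = %d imputed\n",
              x$estimator, x$side, x$k0))
  cat(sprintf("  adjusted d = %.4f, 95%% CI [%.4f, %.4f]\n",
              x$adjusted$mu_hat, x$adjusted$ci_low, x$adjusted$ci_high))
  invisible(x)
}
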