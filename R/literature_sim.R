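# Per-group sample sizes of the packaged field studies, rounded to integers;
# the simulator's default n distribution resamples from these (median 30),
# grounding synthetic literatures in this literature's actual sizes.
packaged_n_pool <- function() {
  r <- priming_studies()$records
  as.integer(round(c(r$n_treatment, r$n_control)))
}

#' Configuration for a synthetic literature
#'
#' @param mu_true true mean standardized effect
#' @param tau between-study SD of true effects (>= 0)
#' @param k_published number of studies that must survive selection
#' @param n_sampler function returning one per-group n; default resamples
#'   with replacement from the packaged studies' (rounded) per-group sizes
#' @param bias_level `"none"`, `"medium"` or `"strong"`: retention
#'   probability 1.0 / 0.2 / 0.05 for studies that are not significant in the
#'   positive direction (significant-positive studies are always retained)
#' @param qrp_level `"none"`, `"medium"` (one operator chosen at random per
#'   study) or `"high"` (all three operators attempted in order
#'   stop -> outlier -> DV-switch, each only while the result is
#'   nonsignificant)
#' @param seed integer RNG seed; simulation is deterministic given the config
#' @return a `sim_config` list
#' @export
sim_config <- function(mu_true = 0, tau = 0, k_published = 10,
                       n_sampler = NULL,
                       bias_level = c("none", "medium", "strong"),
                       qrp_level = c("none", "medium", "high"),
                       seed = 1L) {
  bias_level <- match.arg(bias_level)
  qrp_level <- match.arg(qrp_level)
  if (tau < 0) stop("tau must be non-negative", call. = FALSE)
  if (k_published < 1) stop("k_published must be positive", call. = FALSE)
  if (is.null(n_sampler)) {
    pool <- packaged_n_pool()
    n_sampler <- function() sample(pool, 1)
  }
  structure(list(mu_true = mu_true, tau = tau,
                 k_published = as.integer(k_published),
                 n_sampler = n_sampler, bias_level = bias_level,
                 qrp_level = qrp_level, seed = as.integer(seed)),
            class = "sim_config")
}

two_group_p <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) / (n1 + n2 - 2)
  t <- (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  p_two <- 2 * stats::pt(-abs(t), n1 + n2 - 2)
  list(t = t, p_two = p_two, positive = mean(x1) > mean(x2))
}

sig_pos <- function(test) test$p_two < 0.05 && test$positive

# QRP operators. Each takes the study state (group samples for two correlated
# DVs) and returns the possibly-modified state; they stop early once the
# working result is significant in the positive direction.
qrp_stop <- function(st, theta) {
  for (batch in 1:2) {
    if (sig_pos(two_group_p(st$t1, st$c1))) break
    extra_t <- draw_two_dvs(10, theta)
    extra_c <- draw_two_dvs(10, 0)
    st$t1 <- c(st$t1, extra_t$dv1); st$t2 <- c(st$t2, extra_t$dv2)
    st$c1 <- c(st$c1, extra_c$dv1); st$c2 <- c(st$c2, extra_c$dv2)
  }
  st
}

qrp_outlier <- function(st) {
  for (i in 1:3) {
    if (sig_pos(two_group_p(st$t1, st$c1))) break
    zt <- abs(st$t1 - mean(st$t1)) / stats::sd(st$t1)
    zc <- abs(st$c1 - mean(st$c1)) / stats::sd(st$c1)
    cand <- c(max(zt), max(zc))
    if (max(cand) <= 2) break
    if (which.max(cand) == 1) {
      j <- which.max(zt); st$t1 <- st$t1[-j]; st$t2 <- st$t2[-j]
    } else {
      j <- which.max(zc); st$c1 <- st$c1[-j]; st$c2 <- st$c2[-j]
    }
  }
  st
}

qrp_dv_switch <- function(st) {
  if (!sig_pos(two_group_p(st$t1, st$c1))) {
    p1 <- two_group_p(st$t1, st$c1)$p_two
    p2 <- two_group_p(st$t2, st$c2)$p_two
    if (p2 < p1) {
      st$dv_used <- 2L
      tmp <- st$t1; st$t1 <- st$t2; st$t2 <- tmp
      tmp <- st$c1; st$c1 <- st$c2; st$c2 <- tmp
    }
  }
  st
}

# two DVs per subject, correlated at r = 0.5, both shifted by the group mean
draw_two_dvs <- function(n, mean, r = 0.5) {
  z1 <- stats::rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(n)
  list(dv1 = mean + z1, dv2 = mean + z2)
}

#' Simulate a published literature under selection and QRPs
#'
#' Repeats until `k_published` studies survive: draw a true effect
#' theta_i ~ N(mu_true, tau^2) and a per-group n, simulate two-group normal
#' data (treatment mean theta_i, control 0, SD 1; a second DV correlated at
#' r = 0.5 is carried for the DV-switch operator), apply the configured QRP
#' pipeline, compute the observed d and its two-sided p, then apply the
#' retention rule (significant-positive studies always survive; others with
#' the bias level's retention probability). Published effect sizes are stored
#' on the table scale (small-sample corrected), matching the packaged
#' dataset's convention.
#'
#' @param config a [sim_config()]
#' @return a `simulated_literature` list: `dataset` (a `study_dataset` of the
#'   survivors), `latent` (their true effects), `audit` (data.frame per
#'   published study: theta, initial/final n, operators applied, dv used,
#'   significance), `n_attempted`
#' @export
simulate_literature <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  retention <- c(none = 1.0, medium = 0.2, strong = 0.05)[[config$bias_level]]
  surv <- list()
  audit <- list()
  attempts <- 0L
  while (length(surv) < config$k_published) {
    attempts <- attempts + 1L
    if (attempts > 1e6) {
      stop(sprintf(
        "survival probability too low: %d published after %d attempts",
        length(surv), attempts - 1L), call. = FALSE)
    }
    theta <- stats::rnorm(1, config$mu_true, config$tau)
    n <- config$n_sampler()
    tr <- draw_two_dvs(n, theta)
    ct <- draw_two_dvs(n, 0)
    st <- list(t1 = tr$dv1, t2 = tr$dv2, c1 = ct$dv1, c2 = ct$dv2,
               dv_used = 1L)
    ops <- character(0)
    if (config$qrp_level == "medium") {
      if (!sig_pos(two_group_p(st$t1, st$c1))) {
        op <- sample(c("stop", "outlier", "dv_switch"), 1)
        st <- switch(op,
                     stop = qrp_stop(st, theta),
                     outlier = qrp_outlier(st),
                     dv_switch = qrp_dv_switch(st))
        ops <- op
      }
    } else if (config$qrp_level == "high") {
      if (!sig_pos(two_group_p(st$t1, st$c1))) { st <- qrp_stop(st, theta); ops <- c(ops, "stop") }
      if (!sig_pos(two_group_p(st$t1, st$c1))) { st <- qrp_outlier(st); ops <- c(ops, "outlier") }
      if (!sig_pos(two_group_p(st$t1, st$c1))) { st <- qrp_dv_switch(st); ops <- c(ops, "dv_switch") }
    }
    test <- two_group_p(st$t1, st$c1)
    significant <- sig_pos(test)
    published <- significant || stats::runif(1) < retention
    if (!published) next
    n1 <- length(st$t1); n2 <- length(st$c1)
    sp2 <- ((n1 - 1) * stats::var(st$t1) + (n2 - 1) * stats::var(st$c1)) /
      (n1 + n2 - 2)
    d_raw <- (mean(st$t1) - mean(st$c1)) / sqrt(sp2)
    g <- hedges_j(n1 + n2 - 2) * d_raw
    idx <- length(surv) + 1L
    surv[[idx]] <- data.frame(
      study_id = sprintf("sim_%04d", idx),
      source_label = sprintf("simulated study %d", idx),
      prime_modality = "unknown", prime_specificity = "unknown",
      lag_class = "unknown", dv_label = sprintf("dv%d", st$dv_used),
      n_treatment = n1, n_control = n2, d = g,
      stringsAsFactors = FALSE)
    audit[[idx]] <- data.frame(
      study_id = sprintf("sim_%04d", idx), theta = theta, n_initial = n,
      n_treatment = n1, n_control = n2,
      operators = paste(ops, collapse = "+"), dv_used = st$dv_used,
      significant = significant, stringsAsFactors = FALSE)
  }
  dataset <- study_dataset(do.call(rbind, surv),
                           provenance = sprintf(
                             "simulated literature (mu=%g, tau=%g, bias=%s, qrp=%s, seed=%d)",
                             config$mu_true, config$tau, config$bias_level,
                             config$qrp_level, config$seed))
  structure(list(dataset = dataset,
                 latent = vapply(audit, function(a) a$theta, numeric(1)),
                 audit = do.call(rbind, audit),
                 n_attempted = attempts, config = config),
            class = "simulated_literature")
}

#' Worst-case false-positive rates over a condition grid
#'
#' For each estimator and each null condition (a [sim_config()] with
#' `mu_true = 0`), simulates `reps` literatures and records the proportion in
#' which the estimator falsely rejects H0: mu = 0 in the positive direction
#' (estimate > 0 with two-sided 95% CI excluding 0). Reports each method's
#' worst case over the grid with its Monte Carlo standard error; estimator
#' failures count as non-rejections and are reported as a failure rate.
#'
#' @param conditions list of `sim_config` objects, all with `mu_true = 0`
#' @param methods named list of functions `dataset -> list(estimate, ci_low,
#'   ci_high)`; default [estimator_registry()] without p-curve (which has no
#'   CI and so no rejection rule)
#' @param reps replicates per condition (>= 100 per the design contract)
#' @param seed base seed; replicate seeds are derived deterministically
#' @return an `fpr_table`: `rates` (named percents, worst case per method),
#'   `provenance = "simulated"`, `detail` (per-condition rates), `mc_se_pct`,
#'   `failure_rate`
#' @export
fpr_grid <- function(conditions, methods = NULL, reps = 100, seed = 1L) {
  if (reps < 100) stop("reps must be >= 100 for a usable FPR estimate", call. = FALSE)
  if (!all(vapply(conditions, function(cf) cf$mu_true == 0, logical(1)))) {
    stop("all conditions must have mu_true = 0 (false-positive grid)", call. = FALSE)
  }
  if (is.null(methods)) {
    methods <- estimator_registry()
    methods$p_curve <- NULL
  }
  n_cond <- length(conditions)
  rej <- matrix(0, n_cond, length(methods),
                dimnames = list(NULL, names(methods)))
  fails <- matrix(0, n_cond, length(methods),
                  dimnames = list(NULL, names(methods)))
  for (ci in seq_len(n_cond)) {
    for (r in seq_len(reps)) {
      cf <- conditions[[ci]]
      cf$seed <- (seed + 104729L * ci + r) %% .Machine$integer.max
      lit <- simulate_literature(cf)
      for (mn in names(methods)) {
        est <- tryCatch(methods[[mn]](lit$dataset), error = function(e) NULL)
        if (is.null(est) || !is.finite(est$estimate) ||
            !is.finite(est$ci_low)) {
          fails[ci, mn] <- fails[ci, mn] + 1
        } else if (est$estimate > 0 && est$ci_low > 0) {
          rej[ci, mn] <- rej[ci, mn] + 1
        }
      }
    }
  }
  rate <- 100 * rej / reps
  worst_idx <- apply(rate, 2, which.max)
  rates <- rate[cbind(worst_idx, seq_along(methods))]
  names(rates) <- names(methods)
  p <- rates / 100
  structure(list(rates = rates,
                 provenance = "simulated",
                 detail = rate,
                 mc_se_pct = 100 * sqrt(p * (1 - p) / reps),
                 failure_rate = colSums(fails) / (reps * n_cond)),
            class = "fpr_table")
}

#' @export
print.fpr_table <- function(x, ...) {
  cat(sprintf("worst-case false-positive rates (%s):\n", x$provenance))
  for (m in names(x$rates)) cat(sprintf("  %-14s %5.1f%%\n", m, x$rates[[m]]))
  invisible(x)
}
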