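# Build a study_dataset from bare (d, n1, n2) vectors.
dataset_from_dnn <- function(d, n1, n2, ids = sprintf("s%02d", seq_along(d)),
                             modality = "unknown") {
  study_dataset(data.frame(
    study_id = ids, source_label = ids, prime_modality = modality,
    prime_specificity = "unknown", lag_class = "unknown", dv_label = "",
    n_treatment = n1, n_control = n2, d = d, stringsAsFactors = FALSE))
}

# A perfectly symmetric funnel: pairs of effects mirrored about `center` at
# matched standard errors (several precision tiers).
symmetric_funnel_dataset <- function(center = 0.4,
                                     offsets = c(0.1, 0.25, 0.45, 0.7),
                                     n_tiers = c(200, 100, 50, 25)) {
  d <- c(center + offsets, center - offsets, center)
  n <- c(n_tiers, n_tiers, 400)
  dataset_from_dnn(d, n, n)
}

# Rejection-sample k studies significant in the positive direction from
# two-group normal data with true standardized effect delta; published d is
# stored on the table (g) scale. Gates: "z975" keeps zi > 1.96 (the package's
# inclusion rule), "t95" keeps one-tailed t significance at 0.05 (the p-curve
# conditioning boundary).
sample_significant_studies <- function(k, delta, n_per_group = 30,
                                       gate = c("z975", "t95")) {
  gate <- match.arg(gate)
  d <- numeric(0)
  df <- 2 * n_per_group - 2
  while (length(d) < k) {
    x1 <- rnorm(n_per_group, delta)
    x2 <- rnorm(n_per_group, 0)
    sp <- sqrt(((n_per_group - 1) * var(x1) + (n_per_group - 1) * var(x2)) / df)
    di <- (mean(x1) - mean(x2)) / sp
    vi <- 2 / n_per_group + di^2 / (4 * n_per_group)
    keep <- if (gate == "z975") {
      di / sqrt(vi) > qnorm(0.975)
    } else {
      di * sqrt(n_per_group / 2) > qt(0.95, df)
    }
    if (keep) d <- c(d, hedges_j(df) * di)
  }
  dataset_from_dnn(d, rep(n_per_group, k), rep(n_per_group, k))
}
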