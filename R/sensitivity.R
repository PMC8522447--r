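#' Registry of the eight bias-aware estimators
#'
#' Each entry is a function taking a `study_dataset` and returning
#' `list(estimate, ci_low, ci_high, diagnostics)`; the sensitivity report and
#' the simulation FPR grid both run estimators through this registry, so
#' report entries match standalone module output exactly.
#'
#' @param small_sample effect-scale convention passed through to every
#'   estimator, see [effect_table()]
#' @return named list of estimator functions
#' @export
estimator_registry <- function(small_sample = "printed_g") {
  list(
    random_effects = function(ds) {
      f <- fit_random_effects(ds, small_sample = small_sample)
      list(estimate = f$mu_hat, ci_low = f$ci_low, ci_high = f$ci_high,
           diagnostics = list(tau2 = f$tau2, I2 = f$I2, Q = f$Q,
                              Q_df = f$Q_df, Q_p = f$Q_p))
    },
    PET = function(ds) {
      f <- pet(ds, small_sample = small_sample)
      list(estimate = f$intercept, ci_low = f$intercept_ci[1],
           ci_high = f$intercept_ci[2],
           diagnostics = list(egger_z = f$slope_stat, egger_p = f$slope_p))
    },
    `3PSM` = function(ds) {
      f <- fit_3psm(ds, small_sample = small_sample)
      list(estimate = f$mu, ci_low = f$mu_ci[1], ci_high = f$mu_ci[2],
           diagnostics = list(omega = f$omega, tau2 = f$tau2,
                              lrt_stat = f$lrt_stat, lrt_p = f$lrt_p))
    },
    trim_and_fill = function(ds) {
      f <- trim_and_fill(ds, small_sample = small_sample)
      list(estimate = f$adjusted$mu_hat, ci_low = f$adjusted$ci_low,
           ci_high = f$adjusted$ci_high,
           diagnostics = list(k0 = f$k0, side = f$side))
    },
    PEESE = function(ds) {
      f <- peese(ds, small_sample = small_sample)
      list(estimate = f$intercept, ci_low = f$intercept_ci[1],
           ci_high = f$intercept_ci[2], diagnostics = list())
    },
    PET_PEESE = function(ds) {
      f <- pet_peese(ds, small_sample = small_sample)
      list(estimate = f$intercept, ci_low = f$intercept_ci[1],
           ci_high = f$intercept_ci[2],
           diagnostics = list(selected = f$selected))
    },
    p_curve = function(ds) {
      f <- pcurve_estimate(ds, small_sample = small_sample)
      list(estimate = f$delta_hat, ci_low = NA_real_, ci_high = NA_real_,
           diagnostics = list(loss = f$loss_at_min,
                              n_significant = f$n_significant))
    },
    p_uniform = function(ds) {
      f <- puniform_estimate(ds, small_sample = small_sample)
      list(estimate = f$delta_hat, ci_low = f$ci[1], ci_high = f$ci[2],
           diagnostics = list(n_significant = f$n_significant))
    }
  )
}

#' Packaged worst-case false-positive rates
#'
#' The published worst-case false-positive percentages of the eight
#' estimators under the plausible-condition grid (heterogeneity near
#' tau = 0.4, publication bias none-to-medium, QRPs none-to-high, k near 10),
#' as derived from the external simulation framework's published grid. These
#' are shipped constants, not simulation output of this package; substitute
#' [fpr_grid()] results to recompute under user-defined conditions.
#'
#' @return an `fpr_table` with `provenance = "packaged_paper_values"`
#' @export
packaged_fpr_table <- function() {
  structure(list(rates = c(random_effects = 63, PET = 16, `3PSM` = 14,
                           trim_and_fill = 39, PEESE = 29, PET_PEESE = 22,
                           p_curve = 88, p_uniform = 63),
                 provenance = "packaged_paper_values"),
            class = "fpr_table")
}

#' Admissible estimators under a worst-case FPR threshold
#'
#' Strict-inequality filter: methods whose worst-case false-positive rate is
#' lower than `threshold_pct`, ordered by rate ascending. An empty result is
#' returned as an empty character vector with a message (lowering the
#' threshold can reject every method).
#'
#' @param fpr an `fpr_table`
#' @param threshold_pct threshold in (0, 100); default 20
#' @return character vector of method names, FPR ascending
#' @export
admissible_methods <- function(fpr, threshold_pct = 20) {
  if (threshold_pct <= 0 || threshold_pct > 100) {
    stop("threshold_pct must be in (0, 100]", call. = FALSE)
  }
  rates <- fpr$rates
  keep <- rates[rates < threshold_pct]
  if (length(keep) == 0) {
    message("no method passes the ", threshold_pct, "% worst-case FPR gate")
    return(character(0))
  }
  names(sort(keep))
}

#' Run the full sensitivity analysis
#'
#' Executes all eight estimators with module defaults on `dataset`, attaches
#' each method's worst-case false-positive rate and the admissibility gate
#' (strictly below `threshold_pct`), and returns a serializable report.
#' Estimator failures are captured per method (error message recorded)
#' without aborting the run.
#'
#' @param dataset a `study_dataset`
#' @param fpr an `fpr_table`; default [packaged_fpr_table()]
#' @param threshold_pct admissibility threshold, default 20
#' @param small_sample effect-scale convention, see [effect_table()]
#' @return a `sensitivity_report` list: `methods` (per-method entries
#'   `estimate`, `ci_low`, `ci_high`, `diagnostics`, `fpr_pct`, `admissible`,
#'   `error`), `fpr_provenance`, `threshold_pct`, `admissible_methods`,
#'   `headline` (the admissible methods' estimates), `k`, `total_n`
#' @export
run_full_analysis <- function(dataset, fpr = packaged_fpr_table(),
                              threshold_pct = 20,
                              small_sample = "printed_g") {
  reg <- estimator_registry(small_sample = small_sample)
  adm <- admissible_methods(fpr, threshold_pct)
  methods <- lapply(names(reg), function(mn) {
    est <- tryCatch(reg[[mn]](dataset), error = function(e) {
      list(estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
           diagnostics = list(), error = conditionMessage(e))
    })
    est$fpr_pct <- if (mn %in% names(fpr$rates)) fpr$rates[[mn]] else NA_real_
    est$admissible <- mn %in% adm
    if (is.null(est$error)) est$error <- NA_character_
    est
  })
  names(methods) <- names(reg)
  headline <- lapply(methods[adm], function(m) {
    list(estimate = m$estimate, ci_low = m$ci_low, ci_high = m$ci_high)
  })
  structure(list(methods = methods,
                 fpr_provenance = fpr$provenance,
                 threshold_pct = threshold_pct,
                 admissible_methods = adm,
                 headline = headline,
                 k = n_studies(dataset),
                 total_n = sum(dataset$records$n_treatment +
                                 dataset$records$n_control)),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("sensitivity report: k = %d, total N = %.1f, gate < %g%% FPR (%s)\n",
              x$k, x$total_n, x$threshold_pct, x$fpr_provenance))
  for (mn in names(x$methods)) {
    m <- x$methods[[mn]]
    if (!is.na(m$error)) {
      cat(sprintf("  %-14s failed: %s\n", mn, m$error))
    } else {
      ci <- if (is.na(m$ci_low)) "" else
        sprintf(" [%.2f, %.2f]", m$ci_low, m$ci_high)
      cat(sprintf("  %-14s %6.2f%s  FPR %3.0f%%  %s\n", mn, m$estimate, ci,
                  m$fpr_pct, if (m$admissible) "admissible" else ""))
    }
  }
  invisible(x)
}

#' Serialize a sensitivity report to JSON
#'
#' @param report a `sensitivity_report`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read back a serialized sensitivity report
#'
#' @param path JSON path written by [write_report()]
#' @return a `sensitivity_report`
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  x$admissible_methods <- as.character(unlist(x$admissible_methods))
  structure(x, class = "sensitivity_report")
}
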