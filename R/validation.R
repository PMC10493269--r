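# Canonical validation scenarios for the pipeline. Both use the default
# predictor battery and the reference week imbalance; they differ only in
# the injected outcome model. These are the configurations under which
# the package's recovery and calibration claims are made.

#' Validation scenario configurations
#'
#' `recovery_config()` injects a known sparse effect pattern on the
#' default battery: main effects of 0.75, 1.5 and 3 score units and
#' per-day temporal effects of 0.02 and 0.04, with residual noise of 7
#' score points. All carriers are Likert variables (sd around 1.1-1.4):
#' at the balanced replicate size of roughly 1,000 rows an effect of
#' these magnitudes on a low-prevalence binary is below the design's
#' resolution, so placing them there would test power the design never
#' claims, not recovery. `null_config()` injects no effects at all
#' (intercept 49, noise 7) and is the calibration benchmark for the
#' false-positive rate of the zero-exclusion rule.
#'
#' @param n_total Respondent count (default 20,000).
#' @param seed Generator seed.
#' @return A `wb_sim_config`.
#' @export
recovery_config <- function(n_total = 20000, seed = 20200325) {
  sim_config(
    n_total = n_total,
    true_intercept = 49,
    true_main_effects = c(
      info_satisfaction = 3,
      worry_precarity = -1.5,
      lockdown_agreement = 0.75
    ),
    true_interaction_effects = c(
      worry_ppe = -0.04,
      phone_contacts = 0.02
    ),
    noise_sd = 7,
    seed = seed
  )
}

#' @rdname recovery_config
#' @export
null_config <- function(n_total = 20000, seed = 20200325) {
  sim_config(
    n_total = n_total,
    true_intercept = 49,
    true_main_effects = c(days_since_launch = 0)[0],
    true_interaction_effects = c(days_since_launch = 0)[0],
    noise_sd = 7,
    seed = seed
  )
}

#' Recovery diagnostics against a known truth
#'
#' Compares a coefficient summary with the injected effects of a
#' configuration. The rank correlation is the Spearman correlation
#' between true and estimated absolute effects over the injected
#' (non-zero-truth) terms: over all terms it would be degenerate, since
#' the many exactly-tied zero truths cap the attainable correlation far
#' below one regardless of how well the effects are recovered.
#'
#' @param summary A `wb_coef_summary`.
#' @param truth A [truth_table()] tibble.
#' @return A one-row tibble: `rank_cor` (Spearman over injected effects),
#'   `sign_agreement` and `sig_nonzero` (fractions over injected
#'   effects), `sig_zero` (significant fraction among true zeros),
#'   `n_nonzero`, `n_zero`.
#' @export
recovery_diagnostics <- function(summary, truth) {
  stopifnot(inherits(summary, "wb_coef_summary"))
  tv <- numeric(nrow(summary))
  for (i in seq_len(nrow(summary))) {
    cn <- summary$term[i]
    if (summary$role[i] == "interaction") {
      j <- match(sub(":t$", "", cn), truth$column)
      if (!is.na(j)) tv[i] <- truth$interaction[j]
    } else {
      j <- match(cn, truth$column)
      if (!is.na(j)) tv[i] <- truth$main[j]
    }
  }
  est <- summary$estimate
  nonzero <- tv != 0
  rank_cor <- if (sum(nonzero) >= 3L) {
    stats::cor(abs(tv[nonzero]), abs(est[nonzero]), method = "spearman")
  } else NA_real_
  tibble(
    rank_cor = rank_cor,
    sign_agreement = mean(sign(est[nonzero]) == sign(tv[nonzero])),
    sig_nonzero = mean(summary$significant[nonzero]),
    sig_zero = mean(summary$significant[!nonzero]),
    n_nonzero = sum(nonzero),
    n_zero = sum(!nonzero)
  )
}
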