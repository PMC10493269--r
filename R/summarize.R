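# Percentile inference on the bootstrap ensemble: per coefficient, the
# point estimate B is the median of the draws, the 95% interval the
# empirical 2.5/97.5 percentiles (linear interpolation), and a coefficient
# is "significant" when its interval excludes zero. No p-values and no
# multiplicity correction: zero-exclusion is the whole criterion.

#' Summarize bootstrap coefficient draws
#'
#' @param ensemble A `wb_ensemble`.
#' @param alpha Two-sided level (default 0.05, i.e. 2.5 and 97.5
#'   percentiles).
#' @param scales Optional named multipliers for presentation (e.g. 10 for
#'   a per-day effect reported per 10 days). Defaults to
#'   [default_report_scales()]; terms absent from the map get scale 1.
#' @return A `wb_coef_summary` tibble: `term`, `source`, `role`,
#'   `estimate` (median draw), `conf_low`, `conf_high`, `significant`,
#'   `report_scale`, `estimate_scaled`, `conf_low_scaled`,
#'   `conf_high_scaled`. Attributes record `alpha` and the percentile
#'   interpolation convention (R quantile type 7).
#' @export
summarize_coefficients <- function(ensemble, alpha = 0.05, scales = NULL) {
  stopifnot(inherits(ensemble, "wb_ensemble"))
  if (ensemble$B < 2L) {
    abort("Need at least 2 draws per coefficient.",
          class = "wellridge_validation_error")
  }
  assert_scalar_number(alpha, "alpha", 1e-6, 0.5)
  if (is.null(scales)) scales <- default_report_scales(ensemble)
  terms <- colnames(ensemble$draws)
  est <- apply(ensemble$draws, 2, median)
  ci <- apply(ensemble$draws, 2, wb_quantile,
              probs = c(alpha / 2, 1 - alpha / 2))
  sc <- ifelse(terms %in% names(scales), scales[terms], 1)
  out <- tibble(
    term = terms,
    source = ensemble$info$source[match(terms, ensemble$info$column)],
    role = ensemble$info$role[match(terms, ensemble$info$column)],
    estimate = unname(est),
    conf_low = unname(ci[1L, ]),
    conf_high = unname(ci[2L, ]),
    report_scale = unname(sc)
  ) |>
    dplyr::mutate(
      significant = .data$conf_low > 0 | .data$conf_high < 0,
      estimate_scaled = .data$estimate * .data$report_scale,
      conf_low_scaled = .data$conf_low * .data$report_scale,
      conf_high_scaled = .data$conf_high * .data$report_scale
    ) |>
    dplyr::relocate("significant", .after = "conf_high")
  attr(out, "alpha") <- alpha
  attr(out, "quantile_type") <- 7L
  attr(out, "unscaled_terms") <- setdiff(terms, names(scales))
  class(out) <- c("wb_coef_summary", class(out))
  out
}

#' Default presentation scales
#'
#' Interaction (per-day) effects and the days-since-launch main effect are
#' reported per 10 days; predictors whose schema declares a reporting
#' scale (age: per 10 years) inherit it; everything else is reported per
#' unit.
#'
#' @param ensemble A `wb_ensemble` (or a design `info` tibble).
#' @param per_days Days multiplier for temporal effects (default 10).
#' @param age_scale Multiplier for the `age` source (default 10).
#' @return A named numeric vector over the ensemble's terms.
#' @export
default_report_scales <- function(ensemble, per_days = 10, age_scale = 10) {
  info <- if (inherits(ensemble, "wb_ensemble")) ensemble$info else ensemble
  sc <- rep(1, nrow(info))
  sc[info$role %in% c("interaction", "time")] <- per_days
  sc[info$source == "age" & info$role == "main"] <- age_scale
  stats::setNames(sc, info$column)
}

#' Rescale summarized effects for presentation
#'
#' Multiplies the scaled estimate and interval bounds by `factor` (for
#' instance 10 to report a per-day effect per 10 days). Significance is a
#' zero-exclusion statement and is unchanged by positive rescaling.
#'
#' @param summary A `wb_coef_summary`.
#' @param factor Positive multiplier, either a single number or named per
#'   term.
#' @return The rescaled summary.
#' @export
rescale_effect <- function(summary, factor) {
  stopifnot(inherits(summary, "wb_coef_summary"))
  if (any(!is.finite(factor)) || any(factor <= 0)) {
    abort("`factor` must be positive and finite.",
          class = "wellridge_domain_error")
  }
  f <- if (length(factor) == 1L && is.null(names(factor))) {
    rep(factor, nrow(summary))
  } else {
    ifelse(summary$term %in% names(factor), factor[summary$term], 1)
  }
  summary$report_scale <- summary$report_scale * f
  summary$estimate_scaled <- summary$estimate * summary$report_scale
  summary$conf_low_scaled <- summary$conf_low * summary$report_scale
  summary$conf_high_scaled <- summary$conf_high * summary$report_scale
  summary
}

#' Forest plot of a coefficient summary
#'
#' @param object A `wb_coef_summary`.
#' @param scaled Plot presentation-scaled values (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.wb_coef_summary <- function(object, scaled = TRUE, ...) {
  df <- as_tibble(object)
  if (scaled) {
    df$est <- df$estimate_scaled
    df$lo <- df$conf_low_scaled
    df$hi <- df$conf_high_scaled
  } else {
    df$est <- df$estimate
    df$lo <- df$conf_low
    df$hi <- df$conf_high
  }
  df$term <- stats::reorder(df$term, df$est)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$est, y = .data$term,
                                   colour = .data$significant)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi)) +
    ggplot2::facet_wrap(~role, scales = "free") +
    ggplot2::labs(x = "B (median draw, 95% percentile interval)",
                  y = NULL, colour = "CI excludes 0") +
    ggplot2::theme_minimal()
}
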