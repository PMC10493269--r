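# Grouped effect report: coefficients routed into substantive groups
# (background / COVID-related / coping), split into overall (main) and
# temporal (interaction, time) effects, plus the five-number box summaries
# of each coefficient's bootstrap draws for plotting.

#' Grouped effect report and box-plot data
#'
#' Routes every summarized coefficient into a substantive group via
#' `group_map` (unmapped terms go to `"unassigned"` and are listed in the
#' `unmapped` attribute), flags significant rows, sorts by estimate within
#' group and role, and computes per-term five-number summaries of the
#' bootstrap draws: type-7 quartiles, fences at 1.5 x IQR beyond the
#' quartiles, whiskers at the most extreme draws inside the fences, and
#' the outlying draws beyond them.
#'
#' @param summaries A `wb_coef_summary`.
#' @param ensemble The `wb_ensemble` the summaries came from.
#' @param group_map A tibble or data frame with columns `source` (or
#'   `term`) and `group`.
#' @return A `wb_report` list: `report` (grouped, sorted summary tibble
#'   with a `role_report` of `"main"` or `"temporal"`) and `plot_data`
#'   (per-term `q1`, `median`, `q3`, `fence_low`, `fence_high`,
#'   `whisker_low`, `whisker_high`, `n_outliers`, `outliers` list-col).
#' @export
effect_report <- function(summaries, ensemble, group_map) {
  stopifnot(inherits(summaries, "wb_coef_summary"),
            inherits(ensemble, "wb_ensemble"))
  group_map <- as_tibble(group_map)
  key <- if ("term" %in% names(group_map)) "term" else "source"
  if (!all(c(key, "group") %in% names(group_map))) {
    abort("`group_map` needs columns `group` and `source` (or `term`).",
          class = "wellridge_validation_error")
  }
  idx <- match(summaries[[key]], group_map[[key]])
  report <- as_tibble(summaries) |>
    dplyr::mutate(
      group = ifelse(is.na(idx), "unassigned", group_map$group[idx]),
      role_report = ifelse(.data$role == "main", "main", "temporal")
    ) |>
    dplyr::arrange(.data$group, .data$role_report, .data$estimate)
  unmapped <- unique(report$term[report$group == "unassigned"])
  plot_data <- purrr::map_dfr(colnames(ensemble$draws), function(term) {
    five_number_summary(ensemble$draws[, term]) |>
      dplyr::mutate(term = term, .before = 1)
  }) |>
    dplyr::left_join(dplyr::select(report, "term", "group", "role_report"),
                     by = "term")
  structure(list(report = report, plot_data = plot_data,
                 unmapped = unmapped),
            class = "wb_report")
}

# Box summary of one draw vector: type-7 quartiles, 1.5 x IQR fences,
# whiskers at the most extreme draws inside the fences.
five_number_summary <- function(x) {
  q <- wb_quantile(x, c(0.25, 0.5, 0.75))
  iqr <- q[3L] - q[1L]
  fence_low <- q[1L] - 1.5 * iqr
  fence_high <- q[3L] + 1.5 * iqr
  inside <- x[x >= fence_low & x <= fence_high]
  out <- x[x < fence_low | x > fence_high]
  tibble(q1 = q[1L], median = q[2L], q3 = q[3L],
         fence_low = fence_low, fence_high = fence_high,
         whisker_low = min(inside), whisker_high = max(inside),
         n_outliers = length(out), outliers = list(out))
}

#' @export
print.wb_report <- function(x, ...) {
  cat("<wb_report>\n")
  sig <- dplyr::filter(x$report, .data$significant)
  cat(sprintf("  %d significant / %d terms across %d groups\n",
              nrow(sig), nrow(x$report),
              dplyr::n_distinct(x$report$group)))
  if (length(x$unmapped) > 0L) {
    cat(sprintf("  unmapped terms: %s\n", paste(x$unmapped, collapse = ", ")))
  }
  invisible(x)
}

#' Markdown rendering of an effect report
#'
#' @param x A `wb_report`.
#' @param digits Decimals for estimates and intervals (default 2).
#' @return A character vector of markdown lines.
#' @export
format_report_md <- function(x, digits = 2) {
  stopifnot(inherits(x, "wb_report"))
  fmt <- function(v) formatC(v, format = "f", digits = digits)
  lines <- character()
  for (g in unique(x$report$group)) {
    for (r in c("main", "temporal")) {
      rows <- dplyr::filter(x$report, .data$group == g,
                            .data$role_report == r)
      if (nrow(rows) == 0L) next
      lines <- c(lines, sprintf("## %s — %s effects", g, r), "",
                 "| term | B | 95% CI | significant |",
                 "|---|---|---|---|")
      lines <- c(lines, sprintf(
        "| %s | %s | [%s, %s] | %s |",
        rows$term, fmt(rows$estimate_scaled),
        fmt(rows$conf_low_scaled), fmt(rows$conf_high_scaled),
        ifelse(rows$significant, "yes", "")))
      lines <- c(lines, "")
    }
  }
  lines
}

#' Box plot of bootstrap coefficient draws
#'
#' @param object A `wb_ensemble`.
#' @param terms Optional subset of terms to plot.
#' @param ... Unused.
#' @return A ggplot object built from precomputed five-number summaries.
#' @export
autoplot.wb_ensemble <- function(object, terms = NULL, ...) {
  stats_df <- purrr::map_dfr(colnames(object$draws), function(term) {
    five_number_summary(object$draws[, term]) |>
      dplyr::mutate(term = term, .before = 1)
  })
  if (!is.null(terms)) {
    stats_df <- dplyr::filter(stats_df, .data$term %in% terms)
  }
  stats_df$term <- stats::reorder(stats_df$term, stats_df$median)
  ggplot2::ggplot(stats_df, ggplot2::aes(y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_boxplot(ggplot2::aes(
      xmin = .data$whisker_low, xlower = .data$q1, xmiddle = .data$median,
      xupper = .data$q3, xmax = .data$whisker_high),
      stat = "identity", orientation = "y") +
    ggplot2::labs(x = "bootstrap coefficient draws (score units)",
                  y = NULL) +
    ggplot2::theme_minimal()
}
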