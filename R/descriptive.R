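# Week-by-week descriptive summaries in the style of a survey Table 1:
# per-week and overall respondent counts, outcome mean (sd), and per-level
# counts with percentages of the week's column total.

#' Descriptive week-by-week summary table
#'
#' @param data Survey tibble.
#' @param variables Character vector of categorical variables to
#'   summarise.
#' @param week Name of the week column (default `"week"`).
#' @param outcome Optional name of the numeric outcome column; set to
#'   `NULL` to skip the outcome block (e.g. for count-only fixtures).
#' @return A `wb_descriptive` list with tibbles `counts` (`variable`,
#'   `level`, `week` -- including `"overall"` --, `n`, `pct`) and
#'   `outcome` (`week`, `n`, `mean`, `sd`); percentages are within the
#'   week's column total for that variable.
#' @examples
#' tab <- descriptive_table(reference_respondents(),
#'                          variables = c("sex", "work"), outcome = NULL)
#' dplyr::filter(tab$counts, week == "overall", variable == "sex")
#' @export
descriptive_table <- function(data, variables, week = "week",
                              outcome = "wemwbs_total") {
  missing_vars <- setdiff(c(variables, week), names(data))
  if (length(missing_vars) > 0L) {
    abort(sprintf("Unknown variable(s): %s.",
                  paste(missing_vars, collapse = ", ")),
          class = "wellridge_validation_error")
  }
  wk <- as.character(data[[week]])
  count_one <- function(v) {
    per_week <- tibble(week = wk, level = as.character(data[[v]])) |>
      dplyr::count(.data$week, .data$level)
    overall <- per_week |>
      dplyr::group_by(.data$level) |>
      dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
      dplyr::mutate(week = "overall")
    dplyr::bind_rows(per_week, overall) |>
      dplyr::group_by(.data$week) |>
      dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
      dplyr::ungroup() |>
      dplyr::mutate(variable = v)
  }
  counts <- purrr::map_dfr(variables, count_one) |>
    dplyr::select("variable", "level", "week", "n", "pct")
  out <- list(counts = counts, outcome = NULL)
  if (!is.null(outcome)) {
    if (!outcome %in% names(data)) {
      abort(sprintf("Unknown variable(s): %s.", outcome),
            class = "wellridge_validation_error")
    }
    y <- as.numeric(data[[outcome]])
    per_week <- tibble(week = wk, y = y) |>
      dplyr::group_by(.data$week) |>
      dplyr::summarise(n = dplyr::n(), mean = mean(.data$y),
                       sd = stats::sd(.data$y), .groups = "drop")
    overall <- tibble(week = "overall", n = length(y), mean = mean(y),
                      sd = stats::sd(y))
    out$outcome <- dplyr::bind_rows(per_week, overall)
  }
  structure(out, class = "wb_descriptive")
}

#' @export
print.wb_descriptive <- function(x, ...) {
  cat("<wb_descriptive>\n")
  if (!is.null(x$outcome)) {
    cat("Outcome mean (sd) by week:\n")
    o <- x$outcome
    for (i in seq_len(nrow(o))) {
      cat(sprintf("  %s: n = %d, %.1f (%.1f)\n",
                  o$week[i], o$n[i], o$mean[i], o$sd[i]))
    }
  }
  wide <- x$counts |>
    dplyr::mutate(cell = sprintf("%d (%.1f%%)", .data$n, .data$pct)) |>
    dplyr::select("variable", "level", "week", "cell") |>
    tidyr::pivot_wider(names_from = "week", values_from = "cell")
  print(wide, n = Inf)
  invisible(x)
}
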