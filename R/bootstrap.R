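# Balanced down-sampling bootstrap: each replicate resamples every
# lockdown week with replacement down to the size of the smallest week, so
# all weeks contribute equally, then runs cross-validated ridge on the
# replicate. Coefficient draws are aligned by name across replicates
# because filtering is performed once, globally, before the loop.

balanced_indices <- function(week, seed = NULL) {
  # a factor week keeps its declared levels, so an empty week errors
  if (!is.factor(week)) week <- as.character(week)
  groups <- split(seq_along(week), week)
  sizes <- lengths(groups)
  if (any(sizes == 0L)) {
    abort(sprintf("Week %s has zero rows.",
                  names(groups)[which(sizes == 0L)[1L]]),
          class = "wellridge_validation_error")
  }
  m <- min(sizes)
  # iterate weeks in their sorted label order for determinism
  with_seed_or_local(seed, {
    unlist(purrr::map(groups[order(names(groups))], function(idx) {
      idx[sample.int(length(idx), m, replace = TRUE)]
    }), use.names = FALSE)
  })
}

#' Balanced down-sampling of a survey table
#'
#' Let `m` be the size of the smallest week. Every week contributes
#' exactly `m` rows drawn with replacement from that week's rows -- the
#' minority week included, which is resampled with replacement at its own
#' size -- giving `m x (number of weeks)` rows per replicate. With the
#' reference weekly counts (11,194; 5,008; 629; 1,259; 394; 337; 136)
#' every replicate has 7 x 136 = 952 rows.
#'
#' @param data Survey tibble.
#' @param week Name of the week column (default `"week"`).
#' @param seed Optional integer seed.
#' @return A tibble of `m x n_weeks` resampled rows.
#' @export
balanced_downsample <- function(data, week = "week", seed = NULL) {
  if (!week %in% names(data)) {
    abort(sprintf("Column `%s` is missing.", week),
          class = "wellridge_validation_error")
  }
  if (length(unique(data[[week]])) < 2L) {
    abort("Need at least two weeks to balance.",
          class = "wellridge_validation_error")
  }
  data[balanced_indices(data[[week]], seed = seed), , drop = FALSE]
}

#' Run the balanced bootstrap ensemble
#'
#' Builds the design once from the full table (encoding, time
#' interactions, near-zero-variance and correlation filters -- global, so
#' the coefficient set is identical across replicates), then for each of
#' `B` replicates with deterministically derived child seeds:
#' down-sample weeks to balance, standardize the replicate, select the
#' penalty by `cv_k`-fold cross-validation over `n_lambda` values, refit
#' at the best penalty, and record the original-scale coefficients, the
#' chosen penalty and the replicate's training R^2. Columns that are
#' constant within a replicate get a zero draw and are counted in the
#' degeneracy log.
#'
#' @param data Survey tibble.
#' @param schema Predictor schema.
#' @param B Replicate count (default 1000).
#' @param master_seed Integer master seed; all replicate seeds derive from
#'   it, so serial and parallel execution agree.
#' @param cv_k Folds for penalty selection (default 20).
#' @param n_lambda Penalty-grid length (default 100).
#' @param outcome,time,week Column names.
#' @param freq_ratio_cut,unique_pct_cut Near-zero-variance thresholds.
#' @param cor_threshold Correlation-filter threshold.
#' @return A `wb_ensemble`: `draws` (B x p matrix), `lambda`, `r2`,
#'   `seeds`, `m`, `week_counts`, `degeneracy` log, `info` (column
#'   metadata), `logs` (filter logs), and the run parameters.
#' @export
run_bootstrap <- function(data, schema, B = 1000, master_seed,
                          cv_k = 20, n_lambda = 100,
                          outcome = "wemwbs_total",
                          time = "days_since_launch", week = "week",
                          freq_ratio_cut = 19, unique_pct_cut = 10,
                          cor_threshold = 0.9) {
  stopifnot(B >= 1)
  # Filters run on the main-effect battery, before interaction
  # construction: every `x:t` column shares the time factor, so on
  # week-imbalanced data it is near-collinear with `t` itself and a
  # post-interaction correlation filter would strip the temporal effects
  # the model is built to estimate. Filtering is global (not per
  # replicate) so the coefficient set is identical across replicates.
  design <- build_design(data, schema, outcome = outcome, time = time) |>
    filter_near_zero_variance(freq_ratio_cut = freq_ratio_cut,
                              unique_pct_cut = unique_pct_cut) |>
    filter_correlated(threshold = cor_threshold) |>
    add_time_interactions()
  week_vec <- data[[week]]
  week_counts <- table(as.character(week_vec))
  m <- min(week_counts)
  seeds <- derive_seeds(master_seed, B, streams = 2L)
  p <- ncol(design$X)
  draws <- matrix(NA_real_, B, p, dimnames = list(NULL, colnames(design$X)))
  lambda_b <- numeric(B)
  r2_b <- numeric(B)
  degen <- vector("list", B)
  for (b in seq_len(B)) {
    idx <- balanced_indices(week_vec, seed = seeds[b, 1L])
    rep_design <- subset_design(design, idx)
    cv <- cv_select_lambda(rep_design, k = cv_k, seed = seeds[b, 2L],
                           n_lambda = n_lambda)
    draws[b, ] <- cv$fit$coefficients
    lambda_b[b] <- cv$best_lambda
    r2_b[b] <- cv$fit$r2_train
    # columns constant within this replicate were zeroed by tolerant scaling
    degen[[b]] <- standardize_degenerates(rep_design)
  }
  degeneracy <- tibble(column = unlist(degen, use.names = FALSE)) |>
    dplyr::count(.data$column, name = "n_degenerate")
  structure(
    list(draws = draws, lambda = lambda_b, r2 = r2_b, seeds = seeds,
         B = B, k = cv_k, n_lambda = n_lambda, m = as.integer(m),
         weeks = names(week_counts),
         week_counts = as.integer(week_counts),
         degeneracy = degeneracy, info = design$info, logs = design$logs,
         master_seed = as.integer(master_seed)),
    class = "wb_ensemble"
  )
}

standardize_degenerates <- function(raw_design) {
  sds <- apply(raw_design$X, 2, stats::sd)
  colnames(raw_design$X)[sds == 0 &
                           raw_design$info$role != "time"]
}

#' @export
print.wb_ensemble <- function(x, ...) {
  cat(sprintf("<wb_ensemble> B = %d replicates x %d coefficients\n",
              x$B, ncol(x$draws)))
  cat(sprintf("  balanced weeks: %s (m = %d, %d rows/replicate)\n",
              paste(x$weeks, collapse = ", "), x$m,
              x$m * length(x$weeks)))
  cat(sprintf("  lambda range [%.3g, %.3g], mean train R^2 = %.3f\n",
              min(x$lambda), max(x$lambda), mean(x$r2)))
  invisible(x)
}

#' Tidy a bootstrap ensemble
#'
#' @param x A `wb_ensemble`.
#' @param ... Unused.
#' @return A long tibble of draws: `replicate`, `term`, `estimate`, plus
#'   per-replicate `lambda` and `r2`.
#' @export
tidy.wb_ensemble <- function(x, ...) {
  as_tibble(x$draws) |>
    dplyr::mutate(replicate = dplyr::row_number(),
                  lambda = x$lambda, r2 = x$r2) |>
    tidyr::pivot_longer(cols = -c("replicate", "lambda", "r2"),
                        names_to = "term", values_to = "estimate") |>
    dplyr::select("replicate", "term", "estimate", "lambda", "r2")
}

#' @export
glance.wb_ensemble <- function(x, ...) {
  tibble(B = x$B, n_terms = ncol(x$draws), k = x$k,
         n_lambda = x$n_lambda, m = x$m,
         rows_per_replicate = x$m * length(x$weeks),
         lambda_min = min(x$lambda), lambda_max = max(x$lambda),
         r2_mean = mean(x$r2), r2_min = min(x$r2), r2_max = max(x$r2))
}
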