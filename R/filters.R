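# Predictor filters applied once, on the full design (after interaction
# construction), so that the retained column set is identical across all
# bootstrap replicates and the coefficient ensemble aligns by name.

#' Remove near-zero-variance columns
#'
#' A column is near-zero-variance when the ratio of its most frequent value
#' count to its second most frequent value count is at least
#' `freq_ratio_cut` *and* its percentage of distinct values is at most
#' `unique_pct_cut`. Constant columns are always removed. The removed
#' columns and both statistics are recorded in `logs$nzv`.
#'
#' @param design A `wb_design`.
#' @param freq_ratio_cut Frequency-ratio cutoff (default 95/5 = 19).
#' @param unique_pct_cut Distinct-value percentage cutoff (default 10).
#' @return The filtered design; `design$logs$nzv` holds the removal log
#'   (tibble: `column`, `freq_ratio`, `unique_pct`, `removed`).
#' @export
filter_near_zero_variance <- function(design, freq_ratio_cut = 19,
                                      unique_pct_cut = 10) {
  stopifnot(inherits(design, "wb_design"))
  if (design$standardized) {
    abort("Filter before standardization.", class = "wellridge_structure_error")
  }
  n <- nrow(design$X)
  stats_tbl <- purrr::map_dfr(colnames(design$X), function(cn) {
    v <- design$X[, cn]
    tab <- sort(table(v), decreasing = TRUE)
    freq_ratio <- if (length(tab) == 1L) Inf else unname(tab[1] / tab[2])
    tibble(column = cn,
           freq_ratio = freq_ratio,
           unique_pct = 100 * length(tab) / n)
  })
  stats_tbl$removed <- (stats_tbl$freq_ratio >= freq_ratio_cut &
                          stats_tbl$unique_pct <= unique_pct_cut) |
    !is.finite(stats_tbl$freq_ratio)
  # the time column anchors the interactions; it is never discarded
  stats_tbl$removed[stats_tbl$column == design$time_col &
                      is.finite(stats_tbl$freq_ratio)] <- FALSE
  drop <- stats_tbl$column[stats_tbl$removed]
  keep <- setdiff(colnames(design$X), drop)
  logs <- design$logs
  logs$nzv <- stats_tbl
  new_wb_design(design$X[, keep, drop = FALSE], design$y,
                design$info[match(keep, design$info$column), ],
                time_col = design$time_col, logs = logs)
}

#' Remove highly correlated columns
#'
#' Iteratively finds the pair of columns with the highest absolute Pearson
#' correlation; while that correlation exceeds `threshold`, the member of
#' the pair with the larger mean absolute correlation against all other
#' columns is removed (ties broken by removing the lexicographically later
#' name). The time column is protected: if it belongs to the offending
#' pair, its partner is removed instead.
#'
#' @param design A `wb_design` with at least two columns.
#' @param threshold Absolute correlation above which one of a pair is
#'   dropped (default 0.9).
#' @return The filtered design; `design$logs$correlation` records each
#'   removal (`removed`, `partner`, `correlation`, `mean_abs_cor`).
#' @export
filter_correlated <- function(design, threshold = 0.9) {
  stopifnot(inherits(design, "wb_design"))
  if (design$standardized) {
    abort("Filter before standardization.", class = "wellridge_structure_error")
  }
  X <- design$X
  removed <- list()
  repeat {
    if (ncol(X) < 2L) break
    C <- abs(stats::cor(X))
    diag(C) <- 0
    C[is.na(C)] <- 0
    top <- which(C == max(C), arr.ind = TRUE)[1L, ]
    if (C[top[1L], top[2L]] <= threshold) break
    a <- colnames(X)[top[1L]]
    b <- colnames(X)[top[2L]]
    mean_abs <- rowMeans(C) * ncol(C) / (ncol(C) - 1)  # exclude self (0 on diag)
    pick <- if (mean_abs[a] > mean_abs[b]) a
      else if (mean_abs[b] > mean_abs[a]) b
      else sort(c(a, b))[2L]  # tie: drop the lexicographically later name
    if (pick == design$time_col) pick <- setdiff(c(a, b), pick)
    removed[[length(removed) + 1L]] <- tibble(
      removed = pick, partner = setdiff(c(a, b), pick),
      correlation = C[a, b], mean_abs_cor = unname(mean_abs[pick]))
    X <- X[, setdiff(colnames(X), pick), drop = FALSE]
  }
  logs <- design$logs
  logs$correlation <- if (length(removed)) dplyr::bind_rows(removed) else
    tibble(removed = character(), partner = character(),
           correlation = double(), mean_abs_cor = double())
  keep <- colnames(X)
  new_wb_design(X, design$y, design$info[match(keep, design$info$column), ],
                time_col = design$time_col, logs = logs)
}
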