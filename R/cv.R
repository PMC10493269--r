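# Penalty selection by k-fold cross-validation: fit the ridge path on each
# set of k-1 folds (k = 20 by default, i.e. 95% training / 5% testing per
# fold), predict the held-out fold, pool all out-of-fold predictions, and
# keep the lambda with the largest pooled R^2. Standardization constants
# are computed on each training split only, so no information leaks into
# the held-out rows.

#' Random fold assignment
#'
#' Partitions `n` rows into `k` folds whose sizes differ by at most one.
#'
#' @param n Row count.
#' @param k Fold count (default 20).
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @return An integer vector of length `n` with values in `1..k`.
#' @export
make_folds <- function(n, k = 20, seed = NULL) {
  if (n < k || k < 2L) {
    abort(sprintf("Need n >= k >= 2 (got n = %d, k = %d).", n, k),
          class = "wellridge_domain_error")
  }
  with_seed_or_local(seed, sample(rep_len(seq_len(k), n)))
}

#' Log-spaced descending penalty grid
#'
#' The grid runs from `lambda_max = max_j |x_j' y| / (n * eps_scale)` down
#' to `lambda_max * 1e-4` in `n_lambda` log-equidistant steps. On the
#' standardized scale `|x_j' y| / n` is the marginal covariance of column
#' `j` with the outcome, so the top of the grid shrinks essentially all
#' structure away and the bottom is near-unpenalized.
#'
#' @param design A standardized `wb_design`.
#' @param n_lambda Grid length (default 100).
#' @param eps_scale Divisor controlling the top of the grid (default
#'   0.001).
#' @return A strictly decreasing numeric vector of length `n_lambda`.
#' @export
lambda_grid <- function(design, n_lambda = 100, eps_scale = 1e-3) {
  stopifnot(inherits(design, "wb_design"))
  if (!design$standardized) {
    abort("lambda_grid() expects a standardized design.",
          class = "wellridge_structure_error")
  }
  z <- abs(drop(crossprod(design$X, design$y)))
  if (max(z) <= 0) {
    abort("Degenerate design: X'y is identically zero.",
          class = "wellridge_domain_error")
  }
  lmax <- max(z) / (nrow(design$X) * eps_scale)
  if (n_lambda == 1L) return(lmax)
  exp(seq(log(lmax), log(lmax * 1e-4), length.out = n_lambda))
}

#' Select the penalty by k-fold cross-validation
#'
#' For each fold, the ridge path is fitted on the remaining folds (with
#' standardization constants from those rows only) and the held-out fold
#' is predicted on the original scale. Out-of-fold predictions are pooled
#' over all n rows and one R^2 per lambda is computed; the best lambda
#' (ties broken toward the larger penalty) is then refitted on all rows.
#'
#' @param design A raw (unstandardized) `wb_design` with filters already
#'   applied.
#' @param grid Optional descending penalty grid; by default
#'   [lambda_grid()] of the full standardized design with `n_lambda`
#'   values.
#' @param k Fold count (default 20).
#' @param seed Optional integer seed for the fold assignment.
#' @param n_lambda Grid length when `grid` is `NULL`.
#' @param fold_r2 `"pooled"` (default) pools all out-of-fold predictions
#'   into one R^2 per lambda; `"mean"` averages per-fold R^2 values.
#' @return A `wb_cv` object: `lambda_grid`, `r2_holdout`, `best_lambda`,
#'   `folds`, `k`, and `fit`, the final `wb_ridge_fit` at `best_lambda`.
#' @export
cv_select_lambda <- function(design, grid = NULL, k = 20, seed = NULL,
                             n_lambda = 100, fold_r2 = c("pooled", "mean")) {
  stopifnot(inherits(design, "wb_design"))
  fold_r2 <- match.arg(fold_r2)
  if (design$standardized) {
    abort("cv_select_lambda() expects a raw design (it standardizes per split).",
          class = "wellridge_structure_error")
  }
  n <- nrow(design$X)
  full_std <- standardize_design(design, tolerant = TRUE)
  if (is.null(grid)) grid <- lambda_grid(full_std, n_lambda = n_lambda)
  grid <- sort(grid, decreasing = TRUE)
  folds <- make_folds(n, k = k, seed = seed)
  L <- length(grid)
  preds <- matrix(NA_real_, n, L)
  fold_r2_mat <- matrix(NA_real_, k, L)
  for (f in seq_len(k)) {
    test <- which(folds == f)
    train <- which(folds != f)
    tr <- standardize_design(subset_design(design, train), tolerant = TRUE)
    sv <- design_svd(tr$X, tr$y)
    B_std <- svd_coef_path(sv, grid)                     # p x L
    B_orig <- B_std / tr$info$scale
    intercepts <- tr$y_center - drop(crossprod(B_orig, tr$info$center))
    Xte <- design$X[test, , drop = FALSE]
    preds[test, ] <- sweep(Xte %*% B_orig, 2, intercepts, "+")
    yte <- design$y[test]
    tss_f <- sum((yte - mean(yte))^2)
    if (tss_f > 0) {
      fold_r2_mat[f, ] <- 1 - colSums((yte - preds[test, , drop = FALSE])^2) / tss_f
    }
  }
  tss <- sum((design$y - mean(design$y))^2)
  r2 <- if (fold_r2 == "pooled") {
    1 - colSums((design$y - preds)^2) / tss
  } else {
    colMeans(fold_r2_mat, na.rm = TRUE)
  }
  best_idx <- which.max(r2)  # grid is descending: first max = largest lambda
  best_lambda <- grid[best_idx]
  fit <- fit_ridge(standardize_design(design, tolerant = TRUE), best_lambda)
  structure(
    list(lambda_grid = grid, r2_holdout = r2, best_lambda = best_lambda,
         folds = folds, k = k, fit = fit),
    class = "wb_cv"
  )
}

#' @export
print.wb_cv <- function(x, ...) {
  cat(sprintf("<wb_cv> k = %d, %d lambdas, best lambda = %.4g (held-out R^2 = %.3f)\n",
              x$k, length(x$lambda_grid), x$best_lambda,
              max(x$r2_holdout)))
  invisible(x)
}

#' Tidy a cross-validation result
#'
#' @param x A `wb_cv`.
#' @param ... Unused.
#' @return A tibble with one row per grid value: `lambda`, `r2_holdout`.
#' @export
tidy.wb_cv <- function(x, ...) {
  tibble(lambda = x$lambda_grid, r2_holdout = x$r2_holdout)
}

#' @export
glance.wb_cv <- function(x, ...) {
  tibble(k = x$k, n_lambda = length(x$lambda_grid),
         best_lambda = x$best_lambda,
         r2_holdout_best = max(x$r2_holdout),
         r2_train = x$fit$r2_train)
}
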