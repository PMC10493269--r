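# Ridge (L2) estimator: minimize ||X b - y||^2 + lambda ||b||^2 on the
# standardized scale, solved through a singular-value decomposition that
# is shared across a whole penalty path. The intercept is handled by
# centering and never penalized; reported coefficients are back-transformed
# to the original predictor scale.

# Thin SVD cache for a standardized design.
design_svd <- function(Xs, y) {
  s <- svd(Xs)
  list(d = s$d, V = s$v, Uty = drop(crossprod(s$u, y)))
}

# p x L matrix of standardized-scale coefficients for a lambda vector:
# b(lambda) = V diag(d / (d^2 + lambda)) U'y. Numerically-zero singular
# values are dropped so that lambda = 0 returns the minimum-norm solution.
svd_coef_path <- function(sv, lambdas) {
  keep <- sv$d > max(sv$d[1L], 0) * 1e-12
  d <- sv$d[keep]
  num <- d * sv$Uty[keep]                   # length r
  denom <- outer(d^2, lambdas, "+")         # r x L
  sv$V[, keep, drop = FALSE] %*% (num / denom)
}

check_lambda <- function(lambda) {
  if (!is.numeric(lambda) || any(!is.finite(lambda)) || any(lambda < 0)) {
    abort("`lambda` must be finite and >= 0.", class = "wellridge_domain_error")
  }
  invisible(lambda)
}

new_ridge_fit <- function(lambda, intercept, coefficients, coef_std,
                          r2_train, info) {
  structure(
    list(lambda = lambda, intercept = intercept,
         coefficients = coefficients, coef_std = coef_std,
         r2_train = r2_train, info = info),
    class = "wb_ridge_fit"
  )
}

#' Fit a ridge regression at a single penalty
#'
#' Computes the unique minimizer of `||X b - y||^2 + lambda ||b||^2` on the
#' standardized design via SVD. The intercept is recovered from the stored
#' centering constants and is not penalized; coefficients are returned on
#' the original predictor scale (score units per predictor unit).
#'
#' @param design A standardized `wb_design` (see [standardize_design()]).
#' @param lambda Penalty, a single number `>= 0`.
#' @return A `wb_ridge_fit` with elements `lambda`, `intercept`,
#'   `coefficients` (named, original scale), `coef_std`, `r2_train`.
#' @export
fit_ridge <- function(design, lambda) {
  check_ridge_inputs(design)
  check_lambda(lambda)
  stopifnot(length(lambda) == 1L)
  sv <- design_svd(design$X, design$y)
  b_std <- drop(svd_coef_path(sv, lambda))
  finish_ridge_fit(design, lambda, b_std)
}

check_ridge_inputs <- function(design) {
  stopifnot(inherits(design, "wb_design"))
  if (!design$standardized) {
    abort("fit_ridge() expects a standardized design.",
          class = "wellridge_structure_error")
  }
  if (nrow(design$X) < 2L) {
    abort("Need at least 2 rows.", class = "wellridge_validation_error")
  }
  if (any(!is.finite(design$X)) || any(!is.finite(design$y))) {
    abort("Design contains non-finite values.",
          class = "wellridge_validation_error")
  }
  invisible(design)
}

finish_ridge_fit <- function(design, lambda, b_std) {
  b_orig <- b_std / design$info$scale
  names(b_orig) <- design$info$column
  names(b_std) <- design$info$column
  intercept <- design$y_center - sum(b_orig * design$info$center)
  yhat <- drop(design$X %*% b_std)
  r2 <- 1 - sum((design$y - yhat)^2) / sum(design$y^2)  # y already centered
  new_ridge_fit(lambda, intercept, b_orig, b_std, r2, design$info)
}

#' Fit a whole descending penalty path
#'
#' One SVD of the standardized design is reused for every penalty, giving
#' fits numerically identical to calling [fit_ridge()] per value.
#'
#' @param design A standardized `wb_design`.
#' @param lambdas Non-empty descending penalty grid, strictly positive
#'   except for an optional terminal zero.
#' @return A list of `wb_ridge_fit` objects (class `wb_ridge_path`).
#' @export
ridge_path <- function(design, lambdas) {
  check_ridge_inputs(design)
  check_lambda(lambdas)
  if (length(lambdas) == 0L) {
    abort("Empty lambda grid.", class = "wellridge_domain_error")
  }
  if (any(lambdas[-length(lambdas)] == 0)) {
    abort("Only a terminal zero is allowed in the grid.",
          class = "wellridge_domain_error")
  }
  sv <- design_svd(design$X, design$y)
  B <- svd_coef_path(sv, lambdas)
  fits <- purrr::map(seq_along(lambdas), function(j) {
    finish_ridge_fit(design, lambdas[j], B[, j])
  })
  structure(fits, class = c("wb_ridge_path", "list"))
}

#' Coefficient of determination of a fit on a design
#'
#' `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`, with the mean
#' taken over the evaluated outcome, so held-out evaluations can be
#' negative.
#'
#' @param fit A `wb_ridge_fit`.
#' @param design A `wb_design` (raw or standardized) whose columns align
#'   with the fit.
#' @return A single number `<= 1`.
#' @export
r_squared <- function(fit, design) {
  stopifnot(inherits(fit, "wb_ridge_fit"), inherits(design, "wb_design"))
  if (!identical(colnames(design$X), names(fit$coefficients))) {
    abort("Design columns do not align with the fit.",
          class = "wellridge_structure_error")
  }
  if (design$standardized) {
    y <- design$y + design$y_center
    X <- sweep(sweep(design$X, 2, design$info$scale, "*"),
               2, design$info$center, "+")
  } else {
    y <- design$y
    X <- design$X
  }
  yhat <- fit$intercept + drop(X %*% fit$coefficients)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) {
    abort("Outcome has zero variance; R^2 is undefined.",
          class = "wellridge_domain_error")
  }
  1 - sum((y - yhat)^2) / tss
}

#' @export
print.wb_ridge_fit <- function(x, ...) {
  cat(sprintf("<wb_ridge_fit> lambda = %.4g, train R^2 = %.3f, %d coefficients\n",
              x$lambda, x$r2_train, length(x$coefficients)))
  invisible(x)
}

#' @export
predict.wb_ridge_fit <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "wb_design")) {
    if (newdata$standardized) destandardize_design(newdata)$X else newdata$X
  } else as.matrix(newdata)
  if (!identical(colnames(X), names(object$coefficients))) {
    abort("New data columns do not align with the fit.",
          class = "wellridge_structure_error")
  }
  object$intercept + drop(X %*% object$coefficients)
}

#' Tidy a ridge fit
#'
#' @param x A `wb_ridge_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate` (original scale), `role`,
#'   `source`.
#' @export
tidy.wb_ridge_fit <- function(x, ...) {
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         role = x$info$role,
         source = x$info$source)
}

#' @export
glance.wb_ridge_fit <- function(x, ...) {
  tibble(lambda = x$lambda, r2_train = x$r2_train,
         n_terms = length(x$coefficients))
}
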