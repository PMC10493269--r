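std_random_design <- function(n, p, seed = 1, coef = NULL, noise = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  b <- coef %||% rnorm(p)
  y <- drop(X %*% b) + rnorm(n, sd = noise) + 50
  standardize_design(make_plain_design(X, y))
}

test_that("the unpenalized limit matches ordinary least squares", {
  des <- std_random_design(100, 6, seed = 2)
  fit <- fit_ridge(des, 0)
  raw <- destandardize_design(des)
  ols <- lm(raw$y ~ raw$X)
  expect_lt(max(abs(fit$coefficients - coef(ols)[-1])), 1e-8)
  expect_lt(abs(fit$intercept - coef(ols)[1]), 1e-8)
})

test_that("a single centered predictor follows the closed-form shrinkage", {
  # beta = x'y / (x'x + lambda) = 2 / (2 + 1)
  des <- make_plain_design(matrix(c(-1, 0, 1), ncol = 1), c(-1, 0, 1))
  std <- standardize_design(des)
  fit <- fit_ridge(std, 1)
  expect_equal(unname(fit$coefficients * std$info$scale), 2 / 3,
               tolerance = 1e-12)
})

test_that("infinite shrinkage collapses to the intercept-only model", {
  des <- std_random_design(80, 5, seed = 3)
  fit <- fit_ridge(des, 1e12)
  expect_lt(max(abs(fit$coefficients)), 1e-6)
  expect_equal(fit$intercept, des$y_center, tolerance = 1e-4)
})

test_that("the shared-SVD path equals per-lambda fits", {
  des <- std_random_design(60, 8, seed = 4)
  grid <- exp(seq(log(500), log(0.05), length.out = 40))
  path <- ridge_path(des, grid)
  expect_length(path, 40)
  for (j in c(1, 17, 40)) {
    single <- fit_ridge(des, grid[j])
    expect_equal(path[[j]]$coefficients, single$coefficients,
                 tolerance = 1e-12)
  }
  single_grid <- ridge_path(des, grid[5])
  expect_equal(single_grid[[1]]$coefficients,
               fit_ridge(des, grid[5])$coefficients)
})

test_that("coefficient norms shrink monotonically along the path", {
  des <- std_random_design(70, 10, seed = 5)
  grid <- exp(seq(log(1e4), log(1e-2), length.out = 100))
  norms <- vapply(ridge_path(des, grid), function(f) sqrt(sum(f$coef_std^2)),
                  numeric(1))
  # grid is descending, so norms must be non-decreasing in that order
  expect_true(all(diff(norms) >= -1e-12))
})

test_that("fits agree with a direct penalized solve and with glmnet", {
  skip_if_not_installed("glmnet")
  set.seed(11)
  n <- 200; p <- 30
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X %*% rnorm(p, sd = 0.5)) + rnorm(n) + 30
  des <- standardize_design(make_plain_design(X, y))
  grid <- exp(seq(log(2000), log(0.2), length.out = 100))
  path <- ridge_path(des, grid)
  sd_n <- sqrt(mean((y - mean(y))^2))
  gfit <- glmnet::glmnet(des$X, des$y + des$y_center, alpha = 0,
                         lambda = grid * sd_n / n, standardize = FALSE,
                         thresh = 1e-20)
  for (j in c(1, 25, 60, 100)) {
    direct <- solve(crossprod(des$X) + diag(grid[j], p),
                    crossprod(des$X, des$y))
    expect_lt(max(abs(path[[j]]$coef_std - direct)), 1e-6)
    bg <- as.numeric(coef(gfit)[-1, j])
    expect_lt(max(abs(path[[j]]$coef_std - bg)), 1e-6)
  }
})

test_that("every fit is a local minimum of the penalized objective", {
  des <- std_random_design(50, 6, seed = 6)
  obj <- function(b, lambda) sum((des$y - des$X %*% b)^2) + lambda * sum(b^2)
  for (lambda in c(0.1, 10, 1000)) {
    b <- fit_ridge(des, lambda)$coef_std
    base <- obj(b, lambda)
    for (j in seq_along(b)) {
      for (eps in c(-1e-4, 1e-4)) {
        bp <- b
        bp[j] <- bp[j] + eps
        expect_gte(obj(bp, lambda), base)
      }
    }
  }
})

test_that("R^2 follows its sum-of-squares definition", {
  des <- std_random_design(40, 3, seed = 7, noise = 0.01)
  fit <- fit_ridge(des, 1e-8)
  expect_equal(r_squared(fit, des), 1, tolerance = 1e-3)
  # six-point toy: hand-computed ratio
  Xt <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1)
  yt <- c(2, 2, 4, 5, 5, 8)
  toy <- standardize_design(make_plain_design(Xt, yt))
  f <- fit_ridge(toy, 0)
  yhat <- f$intercept + drop(Xt %*% f$coefficients)
  manual <- 1 - sum((yt - yhat)^2) / sum((yt - mean(yt))^2)
  expect_equal(r_squared(f, destandardize_design(toy)), manual,
               tolerance = 1e-12)
  # intercept-only prediction gives exactly zero
  f0 <- fit_ridge(toy, 1e15)
  expect_equal(r_squared(f0, destandardize_design(toy)), 0, tolerance = 1e-6)
  # zero outcome variance is signalled
  flat <- make_plain_design(Xt, rep(3, 6))
  expect_error(r_squared(f, flat), class = "wellridge_domain_error")
})

test_that("invalid penalties and non-finite designs are rejected", {
  des <- std_random_design(20, 2, seed = 8)
  expect_error(fit_ridge(des, -1), class = "wellridge_domain_error")
  expect_error(ridge_path(des, numeric()), class = "wellridge_domain_error")
  expect_error(ridge_path(des, c(1, 0, 0.5)),
               class = "wellridge_domain_error")
  des$X[1, 1] <- NA
  expect_error(fit_ridge(des, 1), class = "wellridge_validation_error")
  raw <- make_plain_design(matrix(rnorm(20), 10, 2), rnorm(10))
  expect_error(fit_ridge(raw, 1), class = "wellridge_structure_error")
})
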