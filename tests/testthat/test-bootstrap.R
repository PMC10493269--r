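test_that("the reference weekly counts balance to 952 rows", {
  tab <- weekly_count_table()
  out <- balanced_downsample(tab, seed = 1)
  expect_identical(nrow(out), 952L)
  expect_true(all(table(out$week) == 136L))
})

test_that("an already-balanced table keeps its size and balance", {
  tab <- tibble::tibble(week = rep(2:4, each = 25), v = rnorm(75))
  out <- balanced_downsample(tab, seed = 2)
  expect_identical(nrow(out), 75L)
  expect_true(all(table(out$week) == 25L))
})

test_that("within-week resampling is uniform with replacement", {
  tab <- tibble::tibble(week = c(rep(1, 5), rep(2, 3)), id = 1:8)
  counts <- integer(5)
  n_draws <- 2000
  for (s in seq_len(n_draws)) {
    out <- balanced_downsample(tab, seed = s)
    expect_identical(nrow(out), 6L)
    expect_true(all(table(out$week) == 3L))
    # no row crosses weeks
    expect_true(all(out$id[out$week == 1] <= 5))
    counts <- counts + tabulate(out$id[out$week == 1], nbins = 5)
  }
  freq <- counts / (3 * n_draws)
  expect_true(all(abs(freq - 1 / 5) <= 0.02))
})

test_that("an empty declared week is an error naming the week", {
  tab <- tibble::tibble(week = factor(rep(c("2", "3"), 5),
                                      levels = c("2", "3", "8")),
                        v = rnorm(10))
  expect_error(balanced_downsample(tab), "8",
               class = "wellridge_validation_error")
  expect_error(balanced_downsample(tibble::tibble(week = rep(2, 5))),
               class = "wellridge_validation_error")
})

test_that("ensembles are bit-reproducible from the master seed", {
  s <- small_survey(n = 1200, seed = 55)
  e1 <- run_bootstrap(s$data, s$schema, B = 2, master_seed = 77, cv_k = 10,
                      n_lambda = 30)
  e2 <- run_bootstrap(s$data, s$schema, B = 2, master_seed = 77, cv_k = 10,
                      n_lambda = 30)
  expect_identical(e1$draws, e2$draws)
  expect_identical(e1$lambda, e2$lambda)
  e3 <- run_bootstrap(s$data, s$schema, B = 2, master_seed = 78, cv_k = 10,
                      n_lambda = 30)
  expect_false(identical(e1$draws, e3$draws))
})

test_that("every replicate is week-balanced at the minority size", {
  tab <- weekly_count_table()
  seeds <- wellridge:::derive_seeds(123, 5)
  for (b in 1:5) {
    idx <- wellridge:::balanced_indices(tab$week, seed = seeds[b])
    expect_identical(length(idx), 952L)
    expect_true(all(table(tab$week[idx]) == 136L))
  }
})

test_that("a strong injected effect keeps its sign across replicates", {
  specs <- list(pred_likert("driver"), pred_binary("noise_var", 0.5))
  cfg <- sim_config(n_total = 6000, predictor_specs = specs,
                    true_intercept = 45,
                    true_main_effects = c(driver = 2.5),
                    true_interaction_effects = numeric(),
                    noise_sd = 5, seed = 17)
  d <- generate_survey(cfg)
  ens <- run_bootstrap(d, schema_from_config(cfg), B = 100,
                       master_seed = 5, cv_k = 10, n_lambda = 50)
  expect_gte(mean(ens$draws[, "driver"] > 0), 0.95)
})

test_that("columns constant within a replicate draw exactly zero and are logged", {
  set.seed(20)
  n <- 300
  # a predictor present only in week 2 becomes constant whenever the
  # balanced replicate misses its few carriers
  tab <- tibble::tibble(
    wemwbs_total = sample(30:60, n, replace = TRUE),
    days_since_launch = as.integer(rep(c(0, 7, 14), length.out = n)),
    week = rep(2:4, length.out = n),
    solitary = c(rep("yes", 2), rep("no", n - 2)),
    steady = sample(c("no", "yes"), n, replace = TRUE)
  )
  sch <- wb_schema(c("solitary", "steady"), c("binary", "binary"),
                   levels = list(c("no", "yes"), c("no", "yes")),
                   reference = c("no", "no"))
  ens <- run_bootstrap(tab, sch, B = 10, master_seed = 9, cv_k = 5,
                       n_lambda = 20, freq_ratio_cut = 1e6)
  if (nrow(ens$degeneracy) > 0) {
    degen_cols <- ens$degeneracy$column
    expect_true(all(grepl("^solitary", degen_cols)))
    # zero draws in the degenerate replicates
    zero_rows <- rowSums(ens$draws[, degen_cols, drop = FALSE] == 0) > 0
    expect_gte(sum(zero_rows), max(ens$degeneracy$n_degenerate))
  }
  expect_false(anyNA(ens$draws))
})

test_that("median draw magnitudes track the injected effect ordering", {
  cfg <- recovery_config(n_total = 8000, seed = 21)
  d <- generate_survey(cfg)
  ens <- run_bootstrap(d, schema_from_config(cfg), B = 50, master_seed = 31,
                       cv_k = 10, n_lambda = 50)
  s <- summarize_coefficients(ens)
  diag <- recovery_diagnostics(s, truth_table(cfg))
  expect_gte(diag$rank_cor, 0.8)
  expect_equal(diag$sign_agreement, 1)
})
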