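test_that("weekly arrival shares reproduce the configured imbalance", {
  cfg <- sim_config(n_total = 100000, seed = 31)
  d <- generate_survey(cfg)
  share2 <- mean(d$week == 2)
  expect_lt(abs(share2 - 11194 / 18957), 0.01)
  # days-since-launch consistent with the week's 7-day block
  expect_true(all(d$days_since_launch >= 7 * (d$week - 2) &
                    d$days_since_launch <= 7 * (d$week - 2) + 6))
  expect_identical(as.integer(d$response_date - as.Date("2020-03-25")),
                   d$days_since_launch)
})

test_that("noiseless null model yields a constant outcome", {
  cfg <- sim_config(n_total = 500, noise_sd = 0, true_intercept = 49,
                    true_main_effects = numeric(),
                    true_interaction_effects = numeric(), seed = 1)
  d <- generate_survey(cfg)
  expect_true(all(d$wemwbs_total == 49L))
})

test_that("an injected continuous main effect is recovered by least squares", {
  specs <- list(pred_continuous("z", dist = "uniform", range = c(0, 10)))
  cfg <- sim_config(n_total = 50000, predictor_specs = specs,
                    true_intercept = 40,
                    true_main_effects = c(z = 1.5),
                    true_interaction_effects = numeric(),
                    noise_sd = 2, seed = 9)
  d <- generate_survey(cfg)
  slope <- unname(coef(lm(wemwbs_total ~ z, data = d))["z"])
  expect_lt(abs(slope - 1.5), 0.05)
})

test_that("generation is reproducible from the seed and sensitive to it", {
  cfg <- sim_config(n_total = 300, seed = 7)
  expect_identical(generate_survey(cfg), generate_survey(cfg))
  cfg2 <- sim_config(n_total = 300, seed = 8)
  expect_false(identical(generate_survey(cfg), generate_survey(cfg2)))
})

test_that("outcomes are integers within the WEMWBS range", {
  d <- generate_survey(sim_config(n_total = 5000, noise_sd = 25, seed = 3))
  expect_true(all(d$wemwbs_total >= 14L & d$wemwbs_total <= 70L))
  expect_type(d$wemwbs_total, "integer")
})

test_that("empirical marginals converge to the configured marginals", {
  cfg <- sim_config(n_total = 100000, seed = 13)
  d <- generate_survey(cfg)
  tv <- function(emp, conf) sum(abs(emp - conf)) / 2
  edu <- table(factor(d$education,
                      levels = c("up_to_12y", "12_to_14y", "14y_bachelor",
                                 "bachelor_master", "master_phd"))) / nrow(d)
  expect_lte(tv(as.numeric(edu), c(0.166, 0.134, 0.211, 0.385, 0.104)), 0.02)
  expect_lte(tv(c(mean(d$sex_female == "no"), mean(d$sex_female == "yes")),
                c(0.233, 0.767)), 0.02)
  wk <- as.numeric(table(factor(d$week, levels = 2:8))) / nrow(d)
  expect_lte(tv(wk, cfg$week_proportions), 0.02)
})

test_that("with zero noise and no clipping, outcomes are exactly affine", {
  # integer-valued effects on integer carriers keep the linear predictor
  # integral, so integer rounding is a no-op and an exact solve has zero
  # residual
  specs <- list(pred_likert("a"), pred_binary("b", 0.5))
  cfg <- sim_config(n_total = 400, predictor_specs = specs,
                    true_intercept = 40,
                    true_main_effects = c(a = 2, b = -3),
                    true_interaction_effects = numeric(),
                    noise_sd = 0, seed = 5)
  d <- generate_survey(cfg)
  fit <- lm(wemwbs_total ~ a + I(b == "yes"), data = d)
  expect_lt(max(abs(residuals(fit))), 1e-9)
})

test_that("truth table zero-fills and aligns with the encoder output", {
  cfg <- sim_config(n_total = 100,
                    true_main_effects = c(psychiatric_history_current = -2),
                    true_interaction_effects = numeric(), seed = 2)
  tt <- truth_table(cfg)
  expect_identical(sort(tt$column),
                   sort(c("days_since_launch", encoded_column_names(cfg))))
  expect_false(anyDuplicated(tt$column) > 0)
  expect_equal(tt$main[tt$column == "psychiatric_history_current"], -2)
  other <- tt$column != "psychiatric_history_current"
  expect_true(all(tt$main[other] == 0) && all(tt$interaction == 0))
})

test_that("age effects carry the per-10-years reporting convention", {
  cfg <- sim_config(n_total = 100, true_main_effects = c(age = 0.071),
                    true_interaction_effects = numeric(), seed = 2)
  tt <- truth_table(cfg)
  sch <- schema_from_config(cfg)
  scale_age <- sch$report_scale[sch$name == "age"]
  expect_equal(tt$main[tt$column == "age"] * scale_age, 0.71)
})

test_that("configuration errors are specific", {
  expect_error(sim_config(true_main_effects = c(nonexistent_col = 1)),
               "nonexistent_col", class = "wellridge_config_error")
  bad <- list(list(name = "q", kind = "ordinal"))
  expect_error(sim_config(predictor_specs = bad, true_main_effects = numeric(),
                          true_interaction_effects = numeric()),
               "ordinal", class = "wellridge_config_error")
  expect_error(sim_config(week_proportions = rep(0.1, 7)),
               class = "wellridge_config_error")
})
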