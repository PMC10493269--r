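toy_table <- function() {
  tibble::tibble(
    wemwbs_total = c(40L, 50L, 60L),
    days_since_launch = c(0L, 7L, 14L),
    week = c(2L, 3L, 4L),
    colour = c("red", "green", "blue"),
    flag = c("no", "yes", "no"),
    mood = c(1, 3, 5)
  )
}

toy_schema <- function() {
  wb_schema(
    name = c("colour", "flag", "mood"),
    kind = c("categorical", "binary", "likert"),
    levels = list(c("red", "green", "blue"), c("no", "yes"), character()),
    reference = c("red", "no", NA)
  )
}

test_that("categorical predictors expand to reference-omitting dummies", {
  des <- build_design(toy_table(), toy_schema())
  expect_identical(colnames(des$X),
                   c("days_since_launch", "colour_green", "colour_blue",
                     "flag", "mood"))
  # hand-enumerated 3x2 indicator block for the 3-level categorical
  expect_equal(unname(des$X[, c("colour_green", "colour_blue")]),
               rbind(c(0, 0), c(1, 0), c(0, 1)))
  expect_equal(unname(des$X[, "flag"]), c(0, 1, 0))
  expect_equal(unname(des$X[, "mood"]), c(1, 3, 5))
  sch5 <- wb_schema("education", "categorical",
                    levels = list(paste0("lvl", 1:5)), reference = "lvl1")
  d5 <- tibble::tibble(wemwbs_total = rep(40L, 6), days_since_launch = 0:5,
                       education = paste0("lvl", c(1:5, 1)))
  expect_identical(sum(build_design(d5, sch5)$info$source == "education"), 4L)
})

test_that("an all-reference binary encodes as a zero column", {
  d <- toy_table()
  d$flag <- "no"
  des <- build_design(d, toy_schema())
  expect_true(all(des$X[, "flag"] == 0))
})

test_that("unseen category levels are rejected by name", {
  d <- toy_table()
  d$colour[2] <- "mauve"
  expect_error(build_design(d, toy_schema()), "colour.*mauve",
               class = "wellridge_validation_error")
})

test_that("time interactions are elementwise products of main and time", {
  des <- add_time_interactions(build_design(toy_table(), toy_schema()))
  mains <- des$info$column[des$info$role == "main"]
  inters <- des$info$column[des$info$role == "interaction"]
  expect_identical(inters, paste0(mains, ":t"))
  # the time column itself is not interacted with itself
  expect_false("days_since_launch:t" %in% colnames(des$X))
  for (m in mains) {
    expect_equal(des$X[, paste0(m, ":t")],
                 des$X[, m] * des$X[, "days_since_launch"],
                 ignore_attr = TRUE)
  }
  # brute-force product oracle on a random design
  set.seed(42)
  rd <- make_design(matrix(rnorm(15), 5, 3), rnorm(5), time = c(0, 1, 2, 3, 4))
  rdi <- add_time_interactions(rd)
  expect_equal(unname(rdi$X[, c("x1:t", "x2:t", "x3:t")]),
               unname(rd$X[, c("x1", "x2", "x3")] * c(0, 1, 2, 3, 4)))
})

test_that("zero time makes all interaction columns vanish", {
  d <- toy_table()
  d$days_since_launch <- 0L
  des <- add_time_interactions(build_design(d, toy_schema()))
  expect_true(all(des$X[, des$info$role == "interaction"] == 0))
})

test_that("a design without a time column cannot build interactions", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  des <- make_plain_design(X, rnorm(10))
  expect_error(add_time_interactions(des),
               class = "wellridge_structure_error")
})

test_that("standardization centers, scales and round-trips", {
  s <- small_survey(n = 500)
  des <- add_time_interactions(build_design(s$data, s$schema))
  std <- standardize_design(des)
  non_time <- std$info$role != "time"
  expect_lt(max(abs(colMeans(std$X))), 1e-10)
  expect_lt(max(abs(apply(std$X[, non_time], 2, sd) - 1)), 1e-10)
  expect_lt(abs(mean(std$y)), 1e-10)
  back <- destandardize_design(std)
  expect_lt(max(abs(back$X - des$X)), 1e-12)
  expect_lt(max(abs(back$y - des$y)), 1e-12)
  expect_error(standardize_design(std), class = "wellridge_structure_error")
})

test_that("standardizing a constant column is a structural error", {
  X <- cbind(a = rnorm(10), b = rep(2, 10))
  des <- make_plain_design(X, rnorm(10))
  expect_error(standardize_design(des), "b",
               class = "wellridge_structure_error")
  # tolerant mode zeroes the column and logs it instead
  tol <- standardize_design(des, tolerant = TRUE)
  expect_identical(tol$logs$degenerate, "b")
  expect_true(all(tol$X[, "b"] == 0))
})

test_that("column order is deterministic given schema order", {
  s1 <- build_design(toy_table(), toy_schema())
  s2 <- build_design(toy_table(), toy_schema()[c(3, 1, 2), ])
  expect_identical(colnames(s1$X),
                   c("days_since_launch", "colour_green", "colour_blue",
                     "flag", "mood"))
  expect_identical(colnames(s2$X),
                   c("days_since_launch", "mood", "colour_green",
                     "colour_blue", "flag"))
})
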