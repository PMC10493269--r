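# Synthetic respondent-level survey generator. It emulates the statistical
# structure the downstream analysis assumes -- strongly week-imbalanced
# arrival counts, realistic predictor marginals, and a linear outcome
# model on the bounded WEMWBS score with known main and linear-in-time
# interaction effects -- so the whole pipeline is testable without the
# (unavailable) raw survey data.

#' Predictor specification constructors
#'
#' Building blocks for the `predictor_specs` field of [sim_config()].
#' `pred_binary()` draws `"no"`/`"yes"` with `P(yes) = prob_yes`;
#' `pred_categorical()` draws labelled levels with given marginal
#' probabilities (first level is the reference unless stated);
#' `pred_likert()` draws integers on `min..max`; `pred_continuous()` draws
#' from `"uniform"`, `"normal"` (optionally truncated to `range`) or a
#' `"mixture"` of uniform bands with weights.
#'
#' @param name Predictor name (becomes the column name).
#' @param prob_yes Probability of `"yes"` for a binary predictor.
#' @param levels Character level labels.
#' @param probs Marginal probabilities (same length as `levels`, summing
#'   to 1).
#' @param reference Reference level (omitted from dummy coding).
#' @param min,max Likert range (defaults 1 and 5).
#' @param dist Continuous distribution type.
#' @param range Numeric length-2 support bounds.
#' @param mean,sd Normal parameters.
#' @param breaks,weights Mixture bands: `breaks` of length B+1, `weights`
#'   of length B.
#' @return A predictor spec (named list) understood by [sim_config()].
#' @name predictor_specs
NULL

#' @rdname predictor_specs
#' @export
pred_binary <- function(name, prob_yes) {
  assert_scalar_number(prob_yes, "prob_yes", 0, 1)
  list(name = name, kind = "binary", levels = c("no", "yes"),
       reference = "no", probs = c(1 - prob_yes, prob_yes))
}

#' @rdname predictor_specs
#' @export
pred_categorical <- function(name, levels, probs, reference = levels[1]) {
  stopifnot(length(levels) == length(probs), all(probs >= 0),
            abs(sum(probs) - 1) < 1e-8, reference %in% levels)
  list(name = name, kind = "categorical", levels = levels,
       reference = reference, probs = probs)
}

#' @rdname predictor_specs
#' @export
pred_likert <- function(name, min = 1L, max = 5L, probs = NULL) {
  vals <- seq.int(min, max)
  if (is.null(probs)) probs <- rep(1 / length(vals), length(vals))
  stopifnot(length(probs) == length(vals), abs(sum(probs) - 1) < 1e-8)
  list(name = name, kind = "likert", min = min, max = max, probs = probs)
}

#' @rdname predictor_specs
#' @export
pred_continuous <- function(name, dist = c("uniform", "normal", "mixture"),
                            range = c(0, 1), mean = 0, sd = 1,
                            breaks = NULL, weights = NULL) {
  dist <- match.arg(dist)
  if (dist == "mixture") {
    stopifnot(!is.null(breaks), !is.null(weights),
              length(breaks) == length(weights) + 1L,
              abs(sum(weights) - 1) < 1e-8)
  }
  list(name = name, kind = "continuous", dist = dist, range = range,
       mean = mean, sd = sd, breaks = breaks, weights = weights)
}

#' Default predictor battery
#'
#' A ~20-variable battery representative of a lockdown well-being survey:
#' socio-demographics (sex, age, relationship, education, work situation,
#' living area, outdoor access, pet), health (chronic illness, psychiatric
#' history, prior lockdown experience), COVID-related Likert attitudes
#' (agreement with lockdown measures, satisfaction with official
#' information, worries about protective equipment / essential products /
#' precarity, phone contacts) and binary coping/support items. Marginals
#' follow the reference survey's published descriptive proportions where
#' available; Likert and coping marginals, which were not published, use
#' mildly informative defaults.
#'
#' @return A list of predictor specs for [sim_config()].
#' @export
default_predictor_specs <- function() {
  list(
    pred_binary("sex_female", 0.767),
    pred_continuous("age", dist = "mixture",
                    breaks = c(16, 30, 50, 75),
                    weights = c(0.260, 0.475, 0.265)),
    pred_binary("relationship", 0.639),
    pred_categorical("education",
                     levels = c("up_to_12y", "12_to_14y", "14y_bachelor",
                                "bachelor_master", "master_phd"),
                     probs = c(0.166, 0.134, 0.211, 0.385, 0.104)),
    pred_categorical("work",
                     levels = c("employee", "self_employed", "student",
                                "retired", "other"),
                     probs = c(0.663, 0.103, 0.115, 0.076, 0.043)),
    pred_categorical("living_area",
                     levels = c("urban", "semi_rural", "rural"),
                     probs = c(0.541, 0.218, 0.241)),
    pred_binary("outdoor_access", 0.829),
    pred_binary("pet", 0.462),
    pred_binary("ever_locked", 0.203),
    pred_binary("chronic_illness", 0.161),
    pred_categorical("psychiatric_history",
                     levels = c("none", "past", "current"),
                     probs = c(0.748, 0.141, 0.111)),
    pred_likert("phone_contacts", probs = c(0.10, 0.20, 0.30, 0.25, 0.15)),
    pred_likert("lockdown_agreement", probs = c(0.05, 0.10, 0.20, 0.35, 0.30)),
    pred_likert("info_satisfaction", probs = c(0.10, 0.20, 0.35, 0.25, 0.10)),
    pred_likert("worry_ppe", probs = c(0.25, 0.25, 0.20, 0.20, 0.10)),
    pred_likert("worry_products", probs = c(0.30, 0.25, 0.20, 0.15, 0.10)),
    pred_likert("worry_precarity", probs = c(0.35, 0.25, 0.18, 0.12, 0.10)),
    pred_binary("support_neighbors", 0.35),
    pred_binary("coping_favorable_outcome", 0.55),
    pred_binary("coping_resilience", 0.50),
    pred_binary("coping_collective", 0.25),
    pred_binary("coping_positive_self", 0.45)
  )
}

#' Default injected effects
#'
#' Ground-truth effects (score units per encoded-column unit; interactions
#' per day) echoing the magnitudes reported for the reference survey:
#' e.g. current psychiatric issues -2.26, age +0.071 per year, resilience
#' +1.35 as main effects, and a -0.030/day drift of well-being with days
#' in lockdown.
#'
#' @return A list with elements `main` and `interaction`, named numeric
#'   vectors keyed by encoded column names.
#' @export
default_true_effects <- function() {
  list(
    main = c(
      days_since_launch = -0.030,
      age = 0.071,
      psychiatric_history_past = -1.27,
      psychiatric_history_current = -2.26,
      phone_contacts = 0.36,
      info_satisfaction = 0.60,
      lockdown_agreement = 0.60,
      worry_precarity = -0.57,
      worry_products = -0.37,
      coping_resilience = 1.35,
      coping_favorable_outcome = 1.14,
      coping_positive_self = 0.78
    ),
    interaction = c(
      psychiatric_history_current = -0.037,
      worry_ppe = -0.009,
      coping_favorable_outcome = 0.029,
      support_neighbors = 0.024,
      coping_collective = 0.023
    )
  )
}

# day range of lockdown week w, day 0 = survey launch (25 March 2020,
# during week 2 of lockdown): week w spans days 7(w-2) .. 7(w-2)+6.
week_day_range <- function(week) c(7L * (week - 2L), 7L * (week - 2L) + 6L)

#' Simulation configuration
#'
#' Assembles and validates the configuration of the synthetic survey
#' generator. Defaults reproduce the reference study conditions: weeks 2-8
#' with the published weekly arrival proportions, the
#' [default_predictor_specs()] battery, the [default_true_effects()]
#' outcome model, residual noise of 7 score points, and an intercept
#' placing the mean WEMWBS total near 49.
#'
#' @param n_total Number of respondents.
#' @param week_labels Ordered lockdown-week identifiers (default `2:8`).
#' @param week_proportions Probability vector over weeks (default: the
#'   published weekly counts normalized by their total).
#' @param week_day_ranges List of inclusive `c(first, last)`
#'   days-since-launch ranges per week (default: consecutive 7-day
#'   blocks, day 0 = launch).
#' @param predictor_specs List of predictor specs.
#' @param true_intercept Intercept in score units.
#' @param true_main_effects Named vector: encoded column -> effect (score
#'   units per unit).
#' @param true_interaction_effects Named vector: encoded column -> effect
#'   (score units per unit per day).
#' @param noise_sd Residual standard deviation in score units.
#' @param seed Integer seed (mandatory: the generator is fully
#'   reproducible).
#' @return A validated `wb_sim_config`.
#' @export
sim_config <- function(n_total = 18957,
                       week_labels = 2:8,
                       week_proportions = NULL,
                       week_day_ranges = NULL,
                       predictor_specs = default_predictor_specs(),
                       true_intercept = 43.5,
                       true_main_effects = default_true_effects()$main,
                       true_interaction_effects = default_true_effects()$interaction,
                       noise_sd = 7,
                       seed = 20200325) {
  assert_scalar_number(n_total, "n_total", min = length(week_labels))
  assert_scalar_number(noise_sd, "noise_sd", min = 0)
  assert_scalar_number(seed, "seed")
  if (is.null(week_proportions)) {
    wk <- lockdown_week_counts()
    stopifnot(identical(as.integer(week_labels), wk$week))
    week_proportions <- wk$n / sum(wk$n)
  }
  if (length(week_proportions) != length(week_labels) ||
      any(week_proportions <= 0) ||
      abs(sum(week_proportions) - 1) > 1e-12) {
    abort("week_proportions must be positive, align with week_labels and sum to 1.",
          class = "wellridge_config_error")
  }
  if (is.null(week_day_ranges)) {
    week_day_ranges <- purrr::map(week_labels, week_day_range)
  }
  stopifnot(length(week_day_ranges) == length(week_labels))
  kinds <- purrr::map_chr(predictor_specs, "kind")
  bad_kind <- setdiff(kinds, c("binary", "categorical", "likert", "continuous"))
  if (length(bad_kind) > 0L) {
    abort(sprintf("Unknown predictor kind(s): %s.", paste(bad_kind, collapse = ", ")),
          class = "wellridge_config_error")
  }
  cfg <- structure(
    list(n_total = as.integer(n_total), week_labels = week_labels,
         week_proportions = week_proportions,
         week_day_ranges = week_day_ranges,
         predictor_specs = predictor_specs,
         true_intercept = true_intercept,
         true_main_effects = true_main_effects,
         true_interaction_effects = true_interaction_effects,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "wb_sim_config"
  )
  valid_keys <- c("days_since_launch", encoded_column_names(cfg))
  for (eff in list(main = true_main_effects,
                   interaction = true_interaction_effects)) {
    missing <- setdiff(names(eff), valid_keys)
    if (length(missing) > 0L) {
      abort(sprintf("Effect key(s) with no matching encoded column: %s.",
                    paste(missing, collapse = ", ")),
            class = "wellridge_config_error")
    }
  }
  cfg
}

#' Encoded column names implied by a configuration or schema
#'
#' @param x A `wb_sim_config` or schema tibble.
#' @return Character vector of the main-effect column names the encoder
#'   will produce (time column excluded).
#' @export
encoded_column_names <- function(x) {
  specs <- if (inherits(x, "wb_sim_config")) x$predictor_specs else
    schema_to_specs(x)
  unlist(purrr::map(specs, function(s) {
    if (s$kind == "categorical") {
      paste0(s$name, "_", setdiff(s$levels, s$reference))
    } else s$name
  }), use.names = FALSE)
}

#' Derive the analysis schema from a simulation configuration
#'
#' @param config A `wb_sim_config`.
#' @return A schema tibble (`name`, `kind`, `levels`, `reference`,
#'   `report_scale`) accepted by [build_design()]. `report_scale` defaults
#'   to 10 for `age` (effects per 10 years) and 1 otherwise.
#' @export
schema_from_config <- function(config) {
  stopifnot(inherits(config, "wb_sim_config"))
  purrr::map_dfr(config$predictor_specs, function(s) {
    tibble(name = s$name, kind = s$kind,
           levels = list(s$levels %||% character()),
           reference = s$reference %||% NA_character_,
           report_scale = if (s$name == "age") 10 else 1)
  })
}

#' Construct a schema directly
#'
#' @param name,kind,levels,reference,report_scale Vectors (or list for
#'   `levels`) defining one predictor per row.
#' @return A schema tibble.
#' @export
wb_schema <- function(name, kind, levels = NULL, reference = NA_character_,
                      report_scale = 1) {
  tibble(name = name, kind = kind,
         levels = levels %||% purrr::map(name, ~character()),
         reference = reference, report_scale = report_scale)
}

schema_to_specs <- function(schema) {
  purrr::map(seq_len(nrow(schema)), function(i) {
    list(name = schema$name[i], kind = schema$kind[i],
         levels = schema$levels[[i]],
         reference = schema$reference[i])
  })
}

draw_predictor <- function(spec, n) {
  switch(spec$kind,
    binary = sample(spec$levels, n, replace = TRUE, prob = spec$probs),
    categorical = sample(spec$levels, n, replace = TRUE, prob = spec$probs),
    likert = sample(seq.int(spec$min, spec$max), n, replace = TRUE,
                    prob = spec$probs),
    continuous = draw_continuous(spec, n),
    abort(sprintf("Unknown predictor kind `%s`.", spec$kind),
          class = "wellridge_config_error")
  )
}

draw_continuous <- function(spec, n) {
  if (spec$dist == "uniform") {
    runif(n, spec$range[1], spec$range[2])
  } else if (spec$dist == "normal") {
    x <- rnorm(n, spec$mean, spec$sd)
    pmin(pmax(x, spec$range[1]), spec$range[2])
  } else {
    band <- sample(length(spec$weights), n, replace = TRUE,
                   prob = spec$weights)
    runif(n, spec$breaks[band], spec$breaks[band + 1L])
  }
}

#' Generate a synthetic survey table
#'
#' Draws `n_total` respondents: a lockdown week from `week_proportions`, a
#' days-since-launch value uniform within that week's day range,
#' predictors independently from their marginals, and the outcome
#' `y = intercept + sum(main * x) + sum(interaction * x * t) + e`,
#' `e ~ Normal(0, noise_sd)`, rounded to the nearest integer and clipped
#' to the WEMWBS range `[14, 70]`. Fully reproducible from `config$seed`.
#'
#' @param config A `wb_sim_config`.
#' @return A tibble: `id`, `response_date` (ISO, launch 2020-03-25),
#'   `week`, `days_since_launch`, the predictor columns, `wemwbs_total`.
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "wb_sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_total
    widx <- sample(length(config$week_labels), n, replace = TRUE,
                   prob = config$week_proportions)
    lo <- purrr::map_dbl(config$week_day_ranges, 1)
    hi <- purrr::map_dbl(config$week_day_ranges, 2)
    days <- lo[widx] + floor(runif(n) * (hi[widx] - lo[widx] + 1))
    data <- tibble(
      id = sprintf("R%06d", seq_len(n)),
      response_date = as.Date("2020-03-25") + days,
      week = config$week_labels[widx],
      days_since_launch = as.integer(days)
    )
    for (spec in config$predictor_specs) {
      data[[spec$name]] <- draw_predictor(spec, n)
    }
    schema <- schema_from_config(config)
    enc <- encode_predictors(data, schema)
    eta <- rep(config$true_intercept, n)
    main <- config$true_main_effects
    for (key in names(main)) {
      xcol <- if (key == "days_since_launch") data$days_since_launch else
        enc$X[, key]
      eta <- eta + main[[key]] * xcol
    }
    inter <- config$true_interaction_effects
    for (key in names(inter)) {
      xcol <- if (key == "days_since_launch") data$days_since_launch else
        enc$X[, key]
      eta <- eta + inter[[key]] * xcol * data$days_since_launch
    }
    y <- eta + rnorm(n, 0, config$noise_sd)
    data$wemwbs_total <- as.integer(pmin(pmax(round(y), 14L), 70L))
    data
  })
}

#' Ground-truth effect table
#'
#' Aligns the injected effects of a configuration with the encoded column
#' names the pipeline estimates; columns without injected effects map to
#' `(0, 0)`. Reported on the pre-clipping linear scale.
#'
#' @param config A `wb_sim_config`.
#' @param schema Optional schema (defaults to [schema_from_config()]);
#'   must produce the same encoded columns as the configuration.
#' @return A tibble: `column`, `main` (score units per unit),
#'   `interaction` (score units per unit per day).
#' @export
truth_table <- function(config, schema = schema_from_config(config)) {
  stopifnot(inherits(config, "wb_sim_config"))
  cols <- c("days_since_launch", encoded_column_names(schema))
  cfg_cols <- c("days_since_launch", encoded_column_names(config))
  if (!setequal(cols, cfg_cols)) {
    mismatch <- union(setdiff(cols, cfg_cols), setdiff(cfg_cols, cols))
    abort(sprintf("Schema/config column mismatch: %s.",
                  paste(mismatch, collapse = ", ")),
          class = "wellridge_config_error")
  }
  main <- config$true_main_effects
  inter <- config$true_interaction_effects
  tibble(
    column = cols,
    main = unname(ifelse(cols %in% names(main), main[cols], 0)),
    interaction = unname(ifelse(cols %in% names(inter), inter[cols], 0))
  )
}

#' Truth vector aligned to a fitted design
#'
#' Expands a [truth_table()] to one entry per design column: main columns
#' (and the time column) take the `main` effect, `A:t` interaction columns
#' take `A`'s `interaction` effect; anything filtered away is dropped.
#'
#' @param truth A [truth_table()] tibble.
#' @param design A `wb_design` (typically after filtering).
#' @return A named numeric vector over `colnames(design$X)`.
#' @export
truth_for_design <- function(truth, design) {
  stopifnot(inherits(design, "wb_design"))
  info <- design$info
  out <- numeric(nrow(info))
  names(out) <- info$column
  for (i in seq_len(nrow(info))) {
    cn <- info$column[i]
    if (info$role[i] == "interaction") {
      base <- sub(":t$", "", cn)
      j <- match(base, truth$column)
      if (!is.na(j)) out[i] <- truth$interaction[j]
    } else {
      j <- match(cn, truth$column)
      if (!is.na(j)) out[i] <- truth$main[j]
    }
  }
  out
}

#' Write / read a survey table and its sidecars
#'
#' `write_survey()` stores the table as plain CSV (ISO dates) and, when
#' given, the configuration truth as a JSON sidecar next to it.
#'
#' @param data Survey tibble.
#' @param path CSV path.
#' @param config Optional `wb_sim_config` whose [truth_table()] is written
#'   to `<path>_truth.json`.
#' @return `path`, invisibly.
#' @export
write_survey <- function(data, path, config = NULL) {
  readr::write_csv(data, path)
  if (!is.null(config)) {
    truth <- truth_table(config)
    jsonlite::write_json(truth, sub("\\.csv$", "_truth.json", path),
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_survey
#' @export
read_survey <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}
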