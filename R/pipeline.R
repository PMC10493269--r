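# End-to-end orchestration: preprocess -> filters -> balanced bootstrap ->
# percentile inference, with a manifest capturing every seed and threshold
# so a run is fully reconstructible, plus plain-text (CSV/JSON/YAML)
# persistence of ensembles and reports.

#' Run the full analysis pipeline
#'
#' @param data Survey tibble.
#' @param schema Predictor schema.
#' @param B Bootstrap replicate count.
#' @param master_seed Integer master seed (mandatory; every source of
#'   randomness derives from it).
#' @param cv_k,n_lambda Cross-validation folds and penalty-grid length.
#' @param alpha Two-sided level for percentile intervals.
#' @param scales Optional named presentation scales (default
#'   [default_report_scales()]).
#' @param group_map Optional `source`/`group` map for [effect_report()].
#' @param outcome,time,week Column names.
#' @param freq_ratio_cut,unique_pct_cut,cor_threshold Filter thresholds.
#' @param truth Optional [truth_table()] tibble; when given, a recovery
#'   block (sign agreement and rank correlation against the injected
#'   effects) is added to the manifest.
#' @return A `wb_run` list: `ensemble`, `summary`, `report` (or `NULL`),
#'   `manifest`.
#' @export
wb_pipeline <- function(data, schema, B = 1000, master_seed,
                        cv_k = 20, n_lambda = 100, alpha = 0.05,
                        scales = NULL, group_map = NULL,
                        outcome = "wemwbs_total",
                        time = "days_since_launch", week = "week",
                        freq_ratio_cut = 19, unique_pct_cut = 10,
                        cor_threshold = 0.9, truth = NULL) {
  ensemble <- run_bootstrap(
    data, schema, B = B, master_seed = master_seed, cv_k = cv_k,
    n_lambda = n_lambda, outcome = outcome, time = time, week = week,
    freq_ratio_cut = freq_ratio_cut, unique_pct_cut = unique_pct_cut,
    cor_threshold = cor_threshold)
  summary <- summarize_coefficients(ensemble, alpha = alpha, scales = scales)
  report <- if (!is.null(group_map)) {
    effect_report(summary, ensemble, group_map)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("wellridge")),
    master_seed = ensemble$master_seed,
    B = B, cv_k = cv_k, n_lambda = n_lambda, alpha = alpha,
    thresholds = list(freq_ratio_cut = freq_ratio_cut,
                      unique_pct_cut = unique_pct_cut,
                      cor_threshold = cor_threshold),
    n_respondents = nrow(data),
    weeks = ensemble$weeks,
    week_counts = ensemble$week_counts,
    minority_size = ensemble$m,
    rows_per_replicate = ensemble$m * length(ensemble$weeks),
    n_terms = ncol(ensemble$draws),
    removed_nzv = ensemble$logs$nzv$column[ensemble$logs$nzv$removed],
    removed_correlated = ensemble$logs$correlation$removed,
    degeneracy = ensemble$degeneracy
  )
  if (!is.null(truth)) {
    manifest$recovery <- as.list(recovery_diagnostics(summary, truth))
  }
  structure(list(ensemble = ensemble, summary = summary, report = report,
                 manifest = manifest),
            class = "wb_run")
}

#' @export
print.wb_run <- function(x, ...) {
  cat("<wb_run>\n")
  print(x$ensemble)
  cat(sprintf("  %d significant terms at alpha = %.3g\n",
              sum(x$summary$significant), attr(x$summary, "alpha")))
  invisible(x)
}

#' @export
tidy.wb_run <- function(x, ...) as_tibble(x$summary)

#' @export
glance.wb_run <- function(x, ...) glance(x$ensemble)

#' Persist / restore a run
#'
#' `write_run()` writes the coefficient draws (one CSV row per replicate,
#' with `lambda` and `r2` columns), the coefficient summary CSV, a
#' markdown report when present, and a JSON manifest. `read_ensemble()`
#' reconstructs a `wb_ensemble` from such a directory.
#'
#' @param run A `wb_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "wb_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ens <- run$ensemble
  draws <- as_tibble(ens$draws) |>
    dplyr::mutate(.lambda = ens$lambda, .r2 = ens$r2)
  readr::write_csv(draws, file.path(dir, "ensemble.csv"))
  readr::write_csv(as_tibble(run$summary), file.path(dir, "summary.csv"))
  readr::write_csv(ens$info, file.path(dir, "columns.csv"))
  if (!is.null(run$report)) {
    writeLines(format_report_md(run$report), file.path(dir, "report.md"))
  }
  jsonlite::write_json(run$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_run
#' @export
read_ensemble <- function(dir) {
  draws <- readr::read_csv(file.path(dir, "ensemble.csv"),
                           show_col_types = FALSE)
  info <- readr::read_csv(file.path(dir, "columns.csv"),
                          show_col_types = FALSE)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  lambda <- draws$.lambda
  r2 <- draws$.r2
  mat <- as.matrix(dplyr::select(draws, -".lambda", -".r2"))
  if (!setequal(colnames(mat), info$column)) {
    abort("Ensemble columns do not match the stored column metadata.",
          class = "wellridge_validation_error")
  }
  structure(
    list(draws = mat, lambda = lambda, r2 = r2, seeds = NULL,
         B = nrow(mat), k = manifest$cv_k, n_lambda = manifest$n_lambda,
         m = manifest$minority_size, weeks = manifest$weeks,
         week_counts = manifest$week_counts,
         degeneracy = as_tibble(manifest$degeneracy),
         info = info, logs = list(),
         master_seed = manifest$master_seed),
    class = "wb_ensemble"
  )
}

#' Run configuration from YAML
#'
#' Reads and validates a plain-text run configuration with fields
#' mirroring [wb_pipeline()] arguments (`input`, `schema`, `B`, `cv_k`,
#' `n_lambda`, `alpha`, `master_seed`, filter thresholds, `output_dir`,
#' and for simulation runs `n_total` and `noise_sd`). A seed is mandatory:
#' there is no silent nondeterminism.
#'
#' @param path YAML file path, or a named list already in memory.
#' @return A validated named list.
#' @export
run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(cfg$master_seed)) {
    abort("`master_seed` is mandatory in a run configuration.",
          class = "wellridge_config_error")
  }
  defaults <- list(B = 1000, cv_k = 20, n_lambda = 100, alpha = 0.05,
                   freq_ratio_cut = 19, unique_pct_cut = 10,
                   cor_threshold = 0.9, output_dir = "wellridge-output")
  for (nm in names(defaults)) cfg[[nm]] <- cfg[[nm]] %||% defaults[[nm]]
  assert_scalar_number(cfg$B, "B", min = 1)
  assert_scalar_number(cfg$cv_k, "cv_k", min = 2)
  assert_scalar_number(cfg$n_lambda, "n_lambda", min = 1)
  assert_scalar_number(cfg$alpha, "alpha", min = 1e-6, max = 0.5)
  assert_scalar_number(cfg$master_seed, "master_seed")
  cfg
}

#' Orchestrated entry points
#'
#' `run_simulate()` writes a synthetic survey CSV (plus truth sidecar),
#' `run_fit()` runs the full pipeline on an input CSV and persists all
#' artifacts, `run_report()` regenerates summary and report files from a
#' stored ensemble without refitting.
#'
#' @param cfg A [run_config()] list.
#' @return The main artifact path, invisibly.
#' @name run_entry_points
NULL

#' @rdname run_entry_points
#' @export
run_simulate <- function(cfg) {
  cfg <- run_config(cfg)
  config <- sim_config(n_total = cfg$n_total %||% 18957,
                       noise_sd = cfg$noise_sd %||% 7,
                       seed = cfg$master_seed)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(cfg$output_dir, "survey.csv")
  write_survey(generate_survey(config), path, config = config)
  invisible(path)
}

#' @rdname run_entry_points
#' @export
run_fit <- function(cfg) {
  cfg <- run_config(cfg)
  data <- read_survey(cfg$input)
  config <- sim_config(seed = cfg$master_seed)  # default battery schema
  run <- wb_pipeline(data, schema_from_config(config), B = cfg$B,
                     master_seed = cfg$master_seed, cv_k = cfg$cv_k,
                     n_lambda = cfg$n_lambda, alpha = cfg$alpha,
                     freq_ratio_cut = cfg$freq_ratio_cut,
                     unique_pct_cut = cfg$unique_pct_cut,
                     cor_threshold = cfg$cor_threshold)
  write_run(run, cfg$output_dir)
  invisible(cfg$output_dir)
}

#' @rdname run_entry_points
#' @export
run_report <- function(cfg) {
  cfg <- run_config(cfg)
  ensemble <- read_ensemble(cfg$input)
  summary <- summarize_coefficients(ensemble, alpha = cfg$alpha)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(as_tibble(summary),
                   file.path(cfg$output_dir, "summary.csv"))
  invisible(cfg$output_dir)
}
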