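# Design-matrix construction: outcome + reference-coded predictors + a
# days-since-launch time column, later augmented with first-order time
# interactions. The design travels as a light S3 object ("wb_design")
# holding the numeric matrix, the outcome, and per-column metadata.

new_wb_design <- function(X, y, info, time_col,
                          standardized = FALSE, y_center = 0,
                          logs = list()) {
  stopifnot(ncol(X) == nrow(info), length(y) == nrow(X))
  structure(
    list(X = X, y = y, info = info, time_col = time_col,
         standardized = standardized, y_center = y_center, logs = logs),
    class = "wb_design"
  )
}

#' @export
print.wb_design <- function(x, ...) {
  cat(sprintf("<wb_design> %d rows x %d columns (%s)\n",
              nrow(x$X), ncol(x$X),
              if (x$standardized) "standardized" else "raw"))
  cat(sprintf("  roles: %s\n",
              paste(sprintf("%s=%d", names(table(x$info$role)),
                            as.integer(table(x$info$role))), collapse = ", ")))
  invisible(x)
}

#' Per-column metadata of a design
#'
#' @param design A `wb_design`.
#' @return A tibble with one row per design column: `column`, `source`
#'   predictor, `role` (`"time"`, `"main"` or `"interaction"`), `reference`
#'   level (categorical sources only), and the centering/scaling constants
#'   (`NA` until [standardize_design()] has been applied).
#' @export
design_info <- function(design) {
  stopifnot(inherits(design, "wb_design"))
  design$info
}

# Encode the predictor battery of `schema` found in `data` into numeric
# main-effect columns. Binary -> one 0/1 column (1 = non-reference, "yes");
# categorical with L levels -> L-1 dummies omitting the reference; likert
# and continuous -> the numeric value.
encode_predictors <- function(data, schema) {
  cols <- list()
  info <- list()
  for (i in seq_len(nrow(schema))) {
    nm <- schema$name[i]
    kind <- schema$kind[i]
    if (!nm %in% names(data)) {
      abort(sprintf("Predictor `%s` is missing from the data.", nm),
            class = "wellridge_validation_error")
    }
    v <- data[[nm]]
    if (kind == "binary") {
      lv <- schema$levels[[i]]
      ref <- schema$reference[i]
      check_levels(v, lv, nm)
      cols[[nm]] <- as.numeric(v != ref)
      info[[length(info) + 1L]] <- tibble(
        column = nm, source = nm, role = "main", reference = ref)
    } else if (kind == "categorical") {
      lv <- schema$levels[[i]]
      ref <- schema$reference[i]
      check_levels(v, lv, nm)
      for (lev in setdiff(lv, ref)) {
        cn <- paste0(nm, "_", lev)
        cols[[cn]] <- as.numeric(v == lev)
        info[[length(info) + 1L]] <- tibble(
          column = cn, source = nm, role = "main", reference = ref)
      }
    } else if (kind %in% c("likert", "continuous")) {
      if (!is.numeric(v)) {
        abort(sprintf("Predictor `%s` must be numeric (%s).", nm, kind),
              class = "wellridge_validation_error")
      }
      cols[[nm]] <- as.numeric(v)
      info[[length(info) + 1L]] <- tibble(
        column = nm, source = nm, role = "main", reference = NA_character_)
    } else {
      abort(sprintf("Unknown predictor kind `%s` for `%s`.", kind, nm),
            class = "wellridge_config_error")
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, info = dplyr::bind_rows(info))
}

check_levels <- function(v, levels, name) {
  bad <- setdiff(unique(as.character(v)), levels)
  if (length(bad) > 0L) {
    abort(sprintf("Predictor `%s` has level(s) not in the schema: %s.",
                  name, paste(bad, collapse = ", ")),
          class = "wellridge_validation_error")
  }
  invisible(v)
}

#' Build the numeric design from a survey table
#'
#' Encodes the schema's predictors (reference-coded dummies for categorical
#' variables, 0/1 for binary, numeric for Likert/continuous) and prepends
#' the days-since-launch time column. Interactions are added separately by
#' [add_time_interactions()].
#'
#' @param data Respondent-level survey tibble.
#' @param schema Predictor schema tibble as produced by
#'   [schema_from_config()] or [wb_schema()].
#' @param outcome Name of the outcome column (WEMWBS total).
#' @param time Name of the integer days-since-launch column.
#' @return A `wb_design`.
#' @export
build_design <- function(data, schema, outcome = "wemwbs_total",
                         time = "days_since_launch") {
  for (req in c(outcome, time)) {
    if (!req %in% names(data)) {
      abort(sprintf("Column `%s` is missing from the data.", req),
            class = "wellridge_validation_error")
    }
  }
  y <- as.numeric(data[[outcome]])
  tcol <- as.numeric(data[[time]])
  if (anyNA(y) || anyNA(tcol)) {
    abort("Outcome and time columns must be complete (no NA).",
          class = "wellridge_validation_error")
  }
  enc <- encode_predictors(data, schema)
  X <- cbind(matrix(tcol, ncol = 1, dimnames = list(NULL, time)), enc$X)
  info <- dplyr::bind_rows(
    tibble(column = time, source = time, role = "time",
           reference = NA_character_),
    enc$info
  )
  info$center <- NA_real_
  info$scale <- NA_real_
  new_wb_design(X, y, info, time_col = time)
}

#' Append first-order time interactions
#'
#' For every main-effect column `A`, appends a column `A:t` equal to the
#' elementwise product of `A` with the raw days-since-launch column. The
#' time column itself is not interacted with itself, and existing columns
#' are left untouched. Interactions are built on the raw (unstandardized)
#' scale; standardization then treats them as ordinary columns.
#'
#' @param design A raw (unstandardized) `wb_design`.
#' @return The design with one `interaction` column appended per main.
#' @export
add_time_interactions <- function(design) {
  stopifnot(inherits(design, "wb_design"))
  if (design$standardized) {
    abort("Interactions must be built before standardization.",
          class = "wellridge_structure_error")
  }
  if (!design$time_col %in% design$info$column) {
    abort("Design has no time column; cannot build interactions.",
          class = "wellridge_structure_error")
  }
  mains <- design$info$column[design$info$role == "main"]
  if (length(mains) == 0L) {
    abort("Design has no main columns to interact with time.",
          class = "wellridge_structure_error")
  }
  t <- design$X[, design$time_col]
  inter <- design$X[, mains, drop = FALSE] * t
  colnames(inter) <- paste0(mains, ":t")
  info_inter <- tibble(
    column = colnames(inter),
    source = design$info$source[match(mains, design$info$column)],
    role = "interaction",
    reference = design$info$reference[match(mains, design$info$column)],
    center = NA_real_, scale = NA_real_
  )
  new_wb_design(cbind(design$X, inter), design$y,
                dplyr::bind_rows(design$info, info_inter),
                time_col = design$time_col, logs = design$logs)
}

#' Standardize a design for penalized fitting
#'
#' Centers every column and the outcome, and scales every non-time column
#' to unit standard deviation. The constants are stored in the column
#' metadata so fitted coefficients can be reported on the original
#' predictor scale. The ridge penalty is scale-sensitive, so all columns
#' enter the penalty on a comparable footing.
#'
#' @param design A raw `wb_design` (filters already applied).
#' @param tolerant Internal: if `TRUE`, constant columns are recorded in
#'   `logs$degenerate` and left as zero columns (their coefficient is then
#'   exactly zero) instead of raising an error.
#' @return The standardized design.
#' @export
standardize_design <- function(design, tolerant = FALSE) {
  stopifnot(inherits(design, "wb_design"))
  if (design$standardized) {
    abort("Design is already standardized.", class = "wellridge_structure_error")
  }
  X <- design$X
  centers <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  is_time <- design$info$role == "time"
  degenerate <- colnames(X)[sds == 0 & !is_time]
  if (length(degenerate) > 0L && !tolerant) {
    abort(sprintf("Zero-variance column(s) should have been filtered: %s.",
                  paste(degenerate, collapse = ", ")),
          class = "wellridge_structure_error")
  }
  scales <- ifelse(is_time | sds == 0, 1, sds)
  Xs <- sweep(sweep(X, 2, centers, "-"), 2, scales, "/")
  info <- design$info
  info$center <- unname(centers)
  info$scale <- unname(scales)
  logs <- design$logs
  if (length(degenerate) > 0L) logs$degenerate <- degenerate
  out <- new_wb_design(Xs, design$y - mean(design$y), info,
                       time_col = design$time_col, standardized = TRUE,
                       y_center = mean(design$y), logs = logs)
  out
}

#' Undo standardization
#'
#' Restores the raw design from a standardized one using the stored
#' centering/scaling constants; inverse of [standardize_design()] up to
#' floating-point round-off.
#'
#' @param design A standardized `wb_design`.
#' @return The raw design.
#' @export
destandardize_design <- function(design) {
  stopifnot(inherits(design, "wb_design"), design$standardized)
  X <- sweep(sweep(design$X, 2, design$info$scale, "*"),
             2, design$info$center, "+")
  info <- design$info
  info$center <- NA_real_
  info$scale <- NA_real_
  new_wb_design(X, design$y + design$y_center, info,
                time_col = design$time_col, standardized = FALSE,
                logs = design$logs)
}

# Row subset of a raw design (used by the bootstrap).
subset_design <- function(design, idx) {
  stopifnot(!design$standardized)
  new_wb_design(design$X[idx, , drop = FALSE], design$y[idx], design$info,
                time_col = design$time_col, logs = design$logs)
}
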