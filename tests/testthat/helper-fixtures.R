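# Shared fixtures, all built in code.

# A raw wb_design from a plain matrix (mains only + a time column of
# zeros unless supplied), for exercising the linear-algebra layer
# without survey scaffolding.
make_design <- function(X, y, time = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  tcol <- if (is.null(time)) rep(0, nrow(X)) else time
  Xfull <- cbind(t = tcol, X)
  info <- tibble::tibble(
    column = colnames(Xfull),
    source = colnames(Xfull),
    role = c("time", rep("main", ncol(X))),
    reference = NA_character_,
    center = NA_real_, scale = NA_real_
  )
  wellridge:::new_wb_design(Xfull, y, info, time_col = "t")
}

# Mains-only design (no time column at all), for closed-form checks.
make_plain_design <- function(X, y) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  info <- tibble::tibble(
    column = colnames(X), source = colnames(X),
    role = rep("main", ncol(X)),
    reference = NA_character_, center = NA_real_, scale = NA_real_
  )
  wellridge:::new_wb_design(X, y, info, time_col = "t")
}

# Minimal hand-built ensemble around a draws matrix.
make_mock_ensemble <- function(draws, roles = NULL) {
  p <- ncol(draws)
  if (is.null(colnames(draws))) colnames(draws) <- paste0("b", seq_len(p))
  info <- tibble::tibble(
    column = colnames(draws), source = colnames(draws),
    role = roles %||% rep("main", p),
    reference = NA_character_, center = NA_real_, scale = NA_real_
  )
  structure(
    list(draws = draws, lambda = rep(1, nrow(draws)),
         r2 = rep(0.3, nrow(draws)), seeds = NULL, B = nrow(draws),
         k = 20, n_lambda = 100, m = 10, weeks = c("2", "3"),
         week_counts = c(10L, 10L),
         degeneracy = tibble::tibble(column = character(),
                                     n_degenerate = integer()),
         info = info, logs = list(), master_seed = 1L),
    class = "wb_ensemble"
  )
}

`%||%` <- rlang::`%||%`

# Respondent-level expansion of the reference weekly counts (week label
# only), for balance checks.
weekly_count_table <- function() {
  wk <- lockdown_week_counts()
  tibble::tibble(week = rep(wk$week, wk$n))
}

# Small synthetic survey + schema for pipeline-level tests.
small_survey <- function(n = 2000, seed = 421, ...) {
  cfg <- sim_config(n_total = n, seed = seed, ...)
  list(config = cfg, data = generate_survey(cfg),
       schema = schema_from_config(cfg))
}
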