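# Internal helpers shared across modules.

# Deterministic child-seed derivation: one call against the master seed
# yields a B x streams matrix, so replicate b's seeds do not depend on the
# order replicates are executed in.
derive_seeds <- function(master_seed, n, streams = 1L) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  withr::with_seed(
    as.integer(master_seed),
    matrix(sample.int(2147483646L, n * streams), nrow = n, ncol = streams)
  )
}

with_seed_or_local <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single finite number in [%s, %s].",
                  name, format(min), format(max)),
          class = "wellridge_config_error")
  }
  invisible(x)
}

# quantile convention used for all percentile intervals and box summaries:
# linear interpolation between order statistics (R type 7).
wb_quantile <- function(x, probs) {
  stats::quantile(x, probs = probs, names = FALSE, type = 7)
}
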