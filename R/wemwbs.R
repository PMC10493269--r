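#' Score the Warwick-Edinburgh Mental Well-Being Scale (WEMWBS)
#'
#' The WEMWBS is a 14-item self-report measure of mental well-being; each
#' item is answered on a 1-5 scale and the total score is the plain sum,
#' ranging from 14 to 70 with higher scores indicating better well-being.
#'
#' @param items Either a numeric vector of exactly 14 item responses, or a
#'   data frame / matrix with 14 columns (one row per respondent).
#' @return An integer vector of total scores in `[14, 70]` (length 1 for a
#'   vector input, one per row otherwise).
#' @examples
#' score_wemwbs(rep(3, 14))
#' score_wemwbs(rbind(rep(1, 14), rep(5, 14)))
#' @export
score_wemwbs <- function(items) {
  if (is.data.frame(items)) items <- as.matrix(items)
  if (is.matrix(items)) {
    if (ncol(items) != 14L) {
      abort(sprintf("WEMWBS requires exactly 14 items; got %d columns.", ncol(items)),
            class = "wellridge_validation_error")
    }
    check_wemwbs_items(items)
    return(as.integer(rowSums(items)))
  }
  if (!is.numeric(items) || length(items) != 14L) {
    abort(sprintf("WEMWBS requires exactly 14 items; got %d.", length(items)),
          class = "wellridge_validation_error")
  }
  check_wemwbs_items(matrix(items, nrow = 1L))
  as.integer(sum(items))
}

check_wemwbs_items <- function(m) {
  bad <- which(!is.finite(m) | m < 1 | m > 5 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    abort(sprintf("WEMWBS item %d (row %d) is not an integer in 1..5.",
                  bad[1L, "col"], bad[1L, "row"]),
          class = "wellridge_validation_error")
  }
  invisible(m)
}
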