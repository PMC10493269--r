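# Published descriptive margins of the spring-2020 French lockdown
# well-being survey that motivates this package's defaults: weekly arrival
# counts (weeks 2-8 of lockdown, launch 25 March 2020) and per-week level
# counts for the socio-demographic variables. These are the reference
# conditions for the synthetic generator and the worked examples.

#' Weekly respondent counts of the reference lockdown survey
#'
#' Arrival counts per lockdown week (weeks 2 to 8) for the French 2020
#' lockdown well-being survey used as the package's reference scenario.
#' The strong early-week imbalance (11,194 respondents in week 2 down to
#' 136 in week 8) is what the balanced down-sampling bootstrap corrects.
#'
#' @return A tibble with columns `week` (integer, 2-8) and `n`.
#' @examples
#' lockdown_week_counts()
#' sum(lockdown_week_counts()$n)
#' @export
lockdown_week_counts <- function() {
  tibble(
    week = 2:8,
    n = c(11194L, 5008L, 629L, 1259L, 394L, 337L, 136L)
  )
}

#' Per-week descriptive counts of the reference survey
#'
#' Level counts per lockdown week for the categorical socio-demographic and
#' health variables of the reference survey (sex, age band, relationship,
#' education, outdoor access, work situation, prior lockdown experience,
#' chronic illness, psychiatric history, living area, pet ownership).
#'
#' @return A tibble with columns `variable`, `level`, `week`, `n`.
#' @seealso [reference_respondents()] to expand these margins into a
#'   respondent-level fixture, [descriptive_table()] to summarise it.
#' @export
reference_margins <- function() {
  rows <- list(
    sex = list(
      male   = c(2518, 1238, 160, 297, 96, 68, 36),
      female = c(8676, 3770, 469, 962, 298, 269, 100)
    ),
    age_band = list(
      `16-29` = c(3350, 944, 123, 292, 117, 80, 30),
      `30-49` = c(5274, 2487, 294, 562, 171, 161, 64),
      `50-74` = c(2570, 1577, 212, 405, 106, 96, 42)
    ),
    relationship = list(
      no  = c(3940, 1810, 238, 523, 140, 133, 62),
      yes = c(7254, 3198, 391, 736, 254, 204, 74)
    ),
    education = list(
      up_to_12y       = c(1988, 736, 111, 171, 60, 51, 27),
      `12_to_14y`     = c(1498, 667, 93, 167, 59, 44, 19),
      `14y_bachelor`  = c(2435, 1020, 132, 249, 76, 53, 27),
      bachelor_master = c(4157, 1972, 241, 555, 153, 163, 53),
      master_phd      = c(1116, 613, 52, 117, 46, 26, 10)
    ),
    outdoor_access = list(
      no  = c(2001, 787, 89, 226, 65, 52, 19),
      yes = c(9193, 4221, 540, 1033, 329, 285, 117)
    ),
    work = list(
      employee      = c(7388, 3415, 384, 840, 260, 212, 76),
      self_employed = c(1165, 536, 65, 117, 25, 29, 16),
      student       = c(1390, 441, 70, 156, 65, 40, 21),
      retired       = c(763, 446, 74, 94, 21, 26, 11),
      other         = c(488, 170, 36, 52, 23, 30, 12)
    ),
    ever_locked = list(
      no  = c(8922, 4044, 489, 966, 311, 269, 109),
      yes = c(2272, 964, 140, 293, 83, 68, 27)
    ),
    chronic_illness = list(
      no  = c(9446, 4199, 523, 1033, 318, 275, 105),
      yes = c(1748, 809, 106, 226, 76, 62, 31)
    ),
    psychiatric_history = list(
      none    = c(8386, 3850, 448, 898, 289, 216, 86),
      past    = c(1602, 658, 101, 199, 49, 48, 21),
      current = c(1206, 500, 80, 162, 56, 73, 29)
    ),
    living_area = list(
      urban      = c(6192, 2616, 317, 681, 203, 173, 71),
      semi_rural = c(2373, 1101, 158, 286, 98, 76, 34),
      rural      = c(2629, 1291, 154, 292, 93, 88, 31)
    ),
    pet = list(
      no  = c(5845, 2793, 351, 711, 215, 192, 84),
      yes = c(5349, 2215, 278, 548, 179, 145, 52)
    )
  )
  purrr::imap_dfr(rows, function(levels, variable) {
    purrr::imap_dfr(levels, function(n, level) {
      tibble(variable = variable, level = level, week = 2:8, n = as.integer(n))
    })
  })
}

#' Expand the reference margins into a respondent-level fixture
#'
#' Builds a deterministic respondent-level table whose per-week marginal
#' counts for every variable match [reference_margins()] exactly. The joint
#' distribution across variables is arbitrary (variables are filled
#' independently within each week), so the fixture is suitable for
#' verifying descriptive-table arithmetic, not for model fitting.
#'
#' @return A tibble with one row per respondent: `week` plus one column per
#'   reference variable.
#' @examples
#' nrow(reference_respondents())  # 18,957
#' @export
reference_respondents <- function() {
  margins <- reference_margins()
  weeks <- lockdown_week_counts()
  per_week <- purrr::map_dfr(seq_len(nrow(weeks)), function(i) {
    w <- weeks$week[i]
    nw <- weeks$n[i]
    cols <- margins |>
      dplyr::filter(.data$week == w) |>
      dplyr::group_by(.data$variable) |>
      dplyr::summarise(
        values = list(rep(.data$level, times = .data$n)),
        .groups = "drop"
      )
    stopifnot(all(lengths(cols$values) == nw))
    out <- tibble(week = rep(w, nw))
    for (j in seq_len(nrow(cols))) out[[cols$variable[j]]] <- cols$values[[j]]
    out
  })
  per_week
}
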