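#' Number of levels of a matching attribute
#'
#' The chance-match model treats each matching attribute as uniform over a
#' finite number of equally likely levels. This helper counts levels for the
#' common attribute kinds:
#'
#' * a numeric range `c(lo, hi)` of integer-valued measurements counts
#'   half-open, `hi - lo` levels (integer heart rate in `[60, 220)` has
#'   `160` levels — note `[60, 220]` inclusive would give 161);
#' * `"time_of_day"` — time of day at second resolution, 86,400 levels;
#' * `"calendar_date"` — a date window of `days` days, `days` levels.
#'
#' @param kind either a length-2 numeric range `c(lo, hi)` or one of
#'   `"time_of_day"`, `"calendar_date"`.
#' @param days window length in days, required for `"calendar_date"`.
#' @return integer number of levels.
#' @examples
#' attribute_levels(c(60, 220))     # 160
#' attribute_levels("time_of_day")  # 86400
#' @export
attribute_levels <- function(kind, days = NULL) {
  if (is.numeric(kind)) {
    if (length(kind) != 2 || kind[2] <= kind[1])
      abort("numeric range must be c(lo, hi) with hi > lo")
    return(as.integer(kind[2] - kind[1]))
  }
  kind <- match.arg(kind, c("time_of_day", "calendar_date"))
  if (kind == "time_of_day") return(86400L)
  if (is.null(days) || days < 1)
    abort("`days` (>= 1) is required for calendar_date")
  as.integer(days)
}

check_levels <- function(levels) {
  if (!is.numeric(levels) || length(levels) < 1 || any(levels < 1))
    abort("`levels` must be a vector of level counts, all >= 1")
  invisible(levels)
}

#' Probability that two random patients match on all attributes
#'
#' With K independent attributes, the k-th uniform over `m_k` levels, two
#' randomly selected patients agree on attribute k with probability
#' `1 / m_k`, and on all K attributes with probability
#' `p_all = prod(1 / m_k)`.
#'
#' @param levels numeric vector `m_1..m_K` of per-attribute level counts.
#' @return the match probability `p_all`.
#' @examples
#' pair_match_prob(160)          # 0.00625
#' pair_match_prob(c(160, 86400))
#' @export
pair_match_prob <- function(levels) {
  check_levels(levels)
  prod(1 / levels)
}

#' Expected number of chance matches in a cohort
#'
#' Among `n` patients there are `choose(n, 2)` pairs, each matching on all
#' attributes with probability [pair_match_prob()], so the expected number
#' of pairs that collide purely by chance is
#' `E(match) = choose(n, 2) * prod(1 / m_k)`. This is the yardstick for
#' deciding how many attributes (or sampled readings) a release needs before
#' linkage is robust.
#'
#' @param n_patients cohort size (`>= 2`).
#' @inheritParams pair_match_prob
#' @return the expected number of chance-matching pairs.
#' @examples
#' expected_chance_matches(2, 160)           # 0.00625
#' expected_chance_matches(1600, c(160, 86400))
#' @export
expected_chance_matches <- function(n_patients, levels) {
  if (length(n_patients) != 1 || n_patients < 2)
    abort("`n_patients` must be >= 2")
  check_levels(levels)
  choose(n_patients, 2) * pair_match_prob(levels)
}

#' One-row summary of the chance-match model
#'
#' @inheritParams expected_chance_matches
#' @return a tibble with `n_patients`, `n_attributes`, `p_all` and
#'   `expected_matches`.
#' @export
chance_match_summary <- function(n_patients, levels) {
  tibble::tibble(
    n_patients = n_patients,
    n_attributes = length(levels),
    p_all = pair_match_prob(levels),
    expected_matches = expected_chance_matches(n_patients, levels))
}
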