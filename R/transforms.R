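#' Key projections and value transforms
#'
#' Linkage matches records on exact equality of (timestamp, value) pairs.
#' A *projection mode* chooses which component of the timestamp takes part
#' in the match key:
#'
#' * `"datetime"` — the full date-time at second resolution (identity mode);
#' * `"date_only"` — the calendar date (year-month-day), the time of day is
#'   dropped;
#' * `"time_only"` — the time of day at second resolution (86,400 possible
#'   levels), the calendar date is dropped;
#' * `"value_only"` — the timestamp is dropped entirely and records match on
#'   values alone.
#'
#' Coarsening the projection can only merge keys, never split them: if two
#' readings share a `datetime` key they share every coarser key, so match
#' counts are monotone non-decreasing along
#' `datetime -> date_only/time_only -> value_only`.
#'
#' @name projections
NULL

.projection_modes <- c("datetime", "date_only", "time_only", "value_only")

# Canonical integer encoding of a measurement value so that exact-match
# equality and total ordering are well defined:
#  * numeric values are rounded to 1 decimal and scaled by 10;
#  * single lowercase letters (categorical coding) map to 1..26.
canonicalize_value <- function(value) {
  if (is.character(value)) {
    code <- match(value, letters)
    if (anyNA(code)) {
      bad <- unique(value[is.na(code)])
      abort(paste0("categorical values must be single lowercase letters; got: ",
                   paste(head(bad, 5), collapse = ", ")))
    }
    return(as.numeric(code))
  }
  if (!is.numeric(value)) abort("`value` must be numeric or letter-coded character")
  round(value * 10)
}

# Keys are doubles holding exact integers: time component * 1e5 + value
# component. The value component is guaranteed < 1e5 (values < 10,000 bpm),
# the time component < 2^31 seconds, so keys stay below 2^53 and compare
# exactly.
.KEY_VALUE_SPAN <- 1e5

#' Project a reading onto a canonical match key
#'
#' Builds the canonical, totally ordered key on which exact-match linkage
#' operates. Two readings compare equal under a mode iff their projected
#' timestamp components and canonical value components are identical.
#'
#' @param timestamp `POSIXct` vector at whole-second resolution.
#' @param value numeric measurement values (1-decimal heart rates), or
#'   single-lowercase-letter character values produced by
#'   [categorize_values()].
#' @param mode projection mode, one of
#'   `"datetime"`, `"date_only"`, `"time_only"`, `"value_only"`.
#' @return a numeric vector of keys; equality of keys is equality of the
#'   projected (timestamp-component, value-component) pair.
#' @examples
#' ts <- as.POSIXct(c("2020-01-01 10:00:00", "2020-03-05 10:00:00"), tz = "UTC")
#' project_key(ts, c(82.5, 82.5), "time_only")  # equal keys
#' project_key(ts, c(82.5, 82.5), "datetime")   # distinct keys
#' @export
project_key <- function(timestamp, value, mode = "datetime") {
  mode <- match.arg(mode, .projection_modes)
  vcanon <- canonicalize_value(value)
  if (any(vcanon < 0 | vcanon >= .KEY_VALUE_SPAN))
    abort("values out of the encodable range [0, 10000) bpm")
  if (mode == "value_only") return(vcanon)
  if (!inherits(timestamp, "POSIXct"))
    abort("`timestamp` must be POSIXct")
  secs <- round(as.numeric(timestamp))
  tcomp <- switch(mode,
    datetime  = secs,
    date_only = secs %/% 86400,
    time_only = secs %% 86400
  )
  tcomp * .KEY_VALUE_SPAN + vcanon
}

#' Truncate measurement values to integers
#'
#' Replaces every value in a readings table by its integer part (fractions
#' dropped, truncation toward zero). Timestamps are untouched. Emulates
#' releasing integer-valued measurements; truncation coarsens the value
#' component of the match key and can only increase collision rates.
#'
#' @param table a readings table (`ergo` or `pat`) with a numeric `value`
#'   column.
#' @return the table with `value` truncated.
#' @examples
#' tbl <- tibble::tibble(value = c(94.3, 94.0))
#' truncate_values(tbl)$value  # 94 94
#' @export
truncate_values <- function(table) {
  stopifnot(is.data.frame(table), "value" %in% names(table))
  if (any(table$value < 0)) abort("values must be non-negative")
  dplyr::mutate(table, value = trunc(.data$value))
}

#' Recode measurement values as lowercase letters
#'
#' Divides each value by 10, truncates to an integer index in `[0, 25]`, and
#' maps the index onto `a..z`. This turns a numeric series into categorical
#' data (26 levels), the coarsest value coding supported; e.g. the heart
#' rates `c(94.3, 100.5, 130.1, 110.5)` become `c("j", "k", "n", "l")`.
#'
#' @param table a readings table with a numeric `value` column, all values in
#'   `[0, 260)`.
#' @return the table with `value` replaced by single lowercase letters.
#' @export
categorize_values <- function(table) {
  stopifnot(is.data.frame(table), "value" %in% names(table))
  v <- table$value
  if (!is.numeric(v)) abort("`value` must be numeric before letter coding")
  if (any(v < 0 | v >= 260)) {
    bad <- unique(v[v < 0 | v >= 260])
    abort(paste0("values outside [0, 260) cannot be letter-coded: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  dplyr::mutate(table, value = letters[floor(.data$value / 10) + 1])
}
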