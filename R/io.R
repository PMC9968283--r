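# CSV interchange for the three table kinds. Timestamps are written as
# ISO-8601 UTC at second resolution and read back as POSIXct; values keep
# their 1-decimal form.

ts_cols <- function(...) {
  readr::cols(..., timestamp = readr::col_datetime(), .default = readr::col_guess())
}

# drop readr's parsing metadata so round-tripped tables compare clean
strip_readr_attrs <- function(x) {
  attr(x, "spec") <- NULL
  attr(x, "problems") <- NULL
  x
}

#' Read and write the ERGO / PAT / truth CSV files
#'
#' Long-format CSV interchange: `ergo.csv` has one row per reading
#' (`test_id, reading_index, timestamp, value`), `pat.csv` one row per
#' released pair (`released_id, pair_index, timestamp, value`, plus
#' `true_test_id` and/or `subject_id` when present), `truth.csv` one row per
#' test (`test_id, patient_id`). `write_matches_csv()` writes a linkage
#' report as `released_id, max_count, matched_test_ids` with the matched
#' ids `;`-separated.
#'
#' @param path file path.
#' @param ergo,pat,truth,report the corresponding tables.
#' @return the read functions return tibbles; the write functions return
#'   their input invisibly.
#' @name ts_csv
NULL

#' @rdname ts_csv
#' @export
write_ergo_csv <- function(ergo, path) {
  readr::write_csv(ergo, path)
  invisible(ergo)
}

#' @rdname ts_csv
#' @export
read_ergo_csv <- function(path) {
  strip_readr_attrs(readr::read_csv(path, col_types = ts_cols(
    test_id = readr::col_character(),
    reading_index = readr::col_integer(),
    value = readr::col_guess())))
}

#' @rdname ts_csv
#' @export
write_pat_csv <- function(pat, path) {
  readr::write_csv(pat, path)
  invisible(pat)
}

#' @rdname ts_csv
#' @export
read_pat_csv <- function(path) {
  strip_readr_attrs(readr::read_csv(path, col_types = ts_cols(
    released_id = readr::col_character(),
    pair_index = readr::col_integer(),
    value = readr::col_guess())))
}

#' @rdname ts_csv
#' @export
write_truth_csv <- function(truth, path) {
  readr::write_csv(truth, path)
  invisible(truth)
}

#' @rdname ts_csv
#' @export
read_truth_csv <- function(path) {
  strip_readr_attrs(readr::read_csv(
    path, col_types = readr::cols(.default = readr::col_character())))
}

#' @rdname ts_csv
#' @export
write_matches_csv <- function(report, path) {
  out <- tibble::tibble(
    released_id = report$released_id,
    max_count = report$max_count,
    matched_test_ids = purrr::map_chr(report$matched_tests, paste,
                                      collapse = ";"))
  readr::write_csv(out, path)
  invisible(report)
}
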