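# Internal: canonical per-table key/row extraction.
# PAT rows are identified by `released_id` (one record per released row),
# ERGO rows by `test_id`; rows are numbered 1..m / 1..p in first-appearance
# order and the id levels kept for reporting.
pat_keys_rows <- function(pat, mode) {
  stopifnot(is.data.frame(pat),
            all(c("released_id", "timestamp", "value") %in% names(pat)))
  if (nrow(pat) == 0) abort("PAT table is empty")
  ids <- unique(pat$released_id)
  list(key = project_key(pat$timestamp, pat$value, mode),
       row = match(pat$released_id, ids), ids = ids)
}

ergo_keys_rows <- function(ergo, mode) {
  stopifnot(is.data.frame(ergo),
            all(c("test_id", "timestamp", "value") %in% names(ergo)))
  if (nrow(ergo) == 0) abort("ERGO table is empty")
  ids <- unique(ergo$test_id)
  list(key = project_key(ergo$timestamp, ergo$value, mode),
       row = match(ergo$test_id, ids), ids = ids)
}

# group keys by row into flat key vector + 0-based offsets (rows contiguous)
flatten_rows <- function(key, row, nrow) {
  ord <- order(row, key)
  list(key = key[ord], off = c(0L, cumsum(tabulate(row, nrow))))
}

new_linkage_report <- function(res, pat_ids, ergo_ids, algorithm, mode,
                               n_pairs, ops) {
  report <- tibble::tibble(
    released_id = pat_ids,
    max_count = as.integer(res$max_count),
    n_best = lengths(res$argmax),
    matched_tests = lapply(res$argmax, function(k) ergo_ids[k])
  )
  structure(report,
            class = c("linkage_report", class(report)),
            algorithm = algorithm, mode = mode, n_pairs = n_pairs,
            m = length(pat_ids), p = length(ergo_ids), ops = ops)
}

#' Link released records to time series by nested scanning (quadratic
#' baseline)
#'
#' For each released PAT record, counts how many of its n (timestamp, value)
#' pairs occur in each ERGO row by scanning every row of every series —
#' `O(mnpq)` key comparisons for an m-record PAT table and a p-series,
#' q-reading ERGO table. All ERGO rows attaining the maximum count are
#' reported. A pair contributes at most 1 to a row's count however often its
#' key recurs in that row (membership, not multiplicity). Output is
#' identical to [link_sorted()]; use this as the reference matcher on small
#' inputs and [link_sorted()] at scale.
#'
#' @param pat PAT tibble (`released_id, pair_index, timestamp, value`, one
#'   record per `released_id`).
#' @param ergo ERGO tibble (`test_id, reading_index, timestamp, value`).
#' @param mode projection mode, see [project_key()].
#' @return a `linkage_report` tibble: one row per released record with
#'   `max_count` (shared pairs with the best-matching series), `n_best`, and
#'   `matched_tests` (list column; all `test_id`s attaining `max_count`,
#'   empty when `max_count` is 0). Attribute `ops` holds the number of key
#'   comparisons performed.
#' @seealso [link_sorted()], [evaluate_linkage()]
#' @export
link_baseline <- function(pat, ergo, mode = "datetime") {
  mode <- match.arg(mode, .projection_modes)
  s1 <- pat_keys_rows(pat, mode)
  s2 <- ergo_keys_rows(ergo, mode)
  f1 <- flatten_rows(s1$key, s1$row, length(s1$ids))
  f2 <- flatten_rows(s2$key, s2$row, length(s2$ids))
  res <- cpp_baseline_report(f1$key, f1$off, f2$key, f2$off)
  new_linkage_report(res, s1$ids, s2$ids, "baseline", mode,
                     n_pairs = max(diff(f1$off)), ops = res$ops)
}

#' Build the tagged key sequences for sort-merge linkage
#'
#' Flattens both tables into sequences of (key, source-row) pairs: `s1` has
#' one element per PAT pair (`m * n` elements) and `s2` one element per
#' *distinct* key within each ERGO row under the given mode (at most
#' `p * q`; within-row duplicates are dropped so that merge counting has
#' membership semantics). Row tags are 1-based first-appearance indices and
#' do not depend on the mode.
#'
#' @inheritParams link_baseline
#' @return a list of tibbles `s1`, `s2`, each with columns `key`, `row`, in
#'   table order (unsorted), plus the id levels `pat_ids`, `ergo_ids`.
#' @export
build_tagged_sequences <- function(pat, ergo, mode = "datetime") {
  mode <- match.arg(mode, .projection_modes)
  k1 <- pat_keys_rows(pat, mode)
  k2 <- ergo_keys_rows(ergo, mode)
  s2 <- tibble::tibble(key = k2$key, row = k2$row) |>
    dplyr::distinct(.data$row, .data$key) |>
    dplyr::select("key", "row")
  list(s1 = tibble::tibble(key = k1$key, row = k1$row),
       s2 = s2, pat_ids = k1$ids, ergo_ids = k2$ids)
}

check_sorted <- function(s, what) {
  n <- nrow(s)
  if (n < 2) return(invisible(TRUE))
  k <- s$key; r <- s$row
  bad <- k[-1] < k[-n] | (k[-1] == k[-n] & r[-1] < r[-n])
  if (any(bad))
    abort(paste0(what, " is not sorted by (key, row); sort before merging"))
  invisible(TRUE)
}

#' Count shared keys by merging two sorted tagged sequences
#'
#' The core of the sort-merge matcher: one linear pass over the two
#' (key, row)-sorted sequences; within every equal-key block, `count(i, k)`
#' is incremented for each combination of a PAT tag `i` and an ERGO tag `k`.
#' With `s2` de-duplicated within rows (as [build_tagged_sequences()]
#' returns it), the result equals nested-loop membership counting.
#'
#' @param s1,s2 tibbles with columns `key`, `row`, each sorted by
#'   `(key, row)` (an error is raised otherwise).
#' @return a tibble `pat_row, ergo_row, count` of the non-zero entries of the
#'   sparse m-by-p count matrix, sorted by `(pat_row, ergo_row)`; attribute
#'   `ops` holds the number of merge comparisons.
#' @export
merge_count <- function(s1, s2) {
  check_sorted(s1, "s1")
  check_sorted(s2, "s2")
  res <- cpp_merge_count(s1$key, s1$row, s2$key, s2$row)
  out <- tibble::tibble(pat_row = res$pat_row, ergo_row = res$ergo_row,
                        count = res$count) |>
    dplyr::arrange(.data$pat_row, .data$ergo_row)
  attr(out, "ops") <- res$ops
  out
}

#' Link released records to time series by sort-merge
#'
#' The fast matcher: both tables are flattened into tagged key sequences,
#' sorted, and shared keys are counted via equal-key blocks, for a total
#' cost of `O((mn + pq) log(mn + pq) + mp)` instead of the baseline's
#' `O(mnpq)`. The output contract is identical to [link_baseline()]: per
#' released record, all ERGO rows attaining the maximum number of shared
#' (timestamp, value) pairs.
#'
#' @inheritParams link_baseline
#' @return a `linkage_report` tibble; see [link_baseline()]. The `ops`
#'   attribute counts actual sort comparisons plus block-lookup and scan
#'   steps.
#' @examples
#' cohort <- simulate_cohort(5, 2, phase_length = 30, seed = 42)
#' pat <- sample_pat(cohort$ergo, indices = c(0, 29, 59, 89))
#' rep <- link_sorted(pat, cohort$ergo)
#' all(rep$max_count == 4)
#' @export
link_sorted <- function(pat, ergo, mode = "datetime") {
  mode <- match.arg(mode, .projection_modes)
  seqs <- build_tagged_sequences(pat, ergo, mode)
  srt1 <- cpp_sort_tagged(seqs$s1$key, seqs$s1$row)
  srt2 <- cpp_sort_tagged(seqs$s2$key, seqs$s2$row)
  # s1 re-sorted by (row, key) so each record's keys are contiguous for the
  # per-record block accumulation; a permutation, not extra comparisons
  ord <- order(srt1$row, srt1$key)
  res <- cpp_merge_report(srt1$key[ord], srt1$row[ord],
                          srt2$key, srt2$row,
                          m = length(seqs$pat_ids), p = length(seqs$ergo_ids))
  ops <- srt1$ops + srt2$ops + res$ops
  n_pairs <- max(tabulate(seqs$s1$row, length(seqs$pat_ids)))
  new_linkage_report(res, seqs$pat_ids, seqs$ergo_ids, "sorted", mode,
                     n_pairs = n_pairs, ops = ops)
}

#' Score a linkage report against ground truth
#'
#' A released record is a true positive iff its argmax set is exactly the
#' singleton containing its true test; ties, misses and empty argmax sets
#' all count as false positives, so `TP + FP = m` always. The false-positive
#' rate is `FP / (TP + FP)` and accuracy is `TP / (TP + FP)`.
#'
#' @param report a `linkage_report` from [link_baseline()] or
#'   [link_sorted()].
#' @param truth a data frame mapping `released_id` to `true_test_id` (a PAT
#'   table sampled with `keep_truth = TRUE` works as-is).
#' @return a `linkage_eval` object; use [glance()] for the one-row
#'   `TP/FP/FPR/accuracy` summary and [tidy()] for the per-record outcomes.
#' @export
evaluate_linkage <- function(report, truth) {
  stopifnot(inherits(report, "linkage_report"),
            all(c("released_id", "true_test_id") %in% names(truth)))
  truth <- dplyr::distinct(
    dplyr::select(truth, "released_id", "true_test_id"))
  missing <- setdiff(report$released_id, truth$released_id)
  if (length(missing) > 0)
    abort(paste0("no ground truth for released record(s): ",
                 paste(head(missing, 5), collapse = ", ")))
  per <- dplyr::left_join(tibble::as_tibble(report), truth,
                          by = "released_id") |>
    dplyr::mutate(
      correct = purrr::map2_lgl(.data$matched_tests, .data$true_test_id,
                                function(mt, tt) length(mt) == 1 && mt == tt)
    )
  tp <- sum(per$correct)
  m <- nrow(per)
  structure(
    list(TP = tp, FP = m - tp, m = m, FPR = (m - tp) / m,
         accuracy = tp / m, per_record = per,
         algorithm = attr(report, "algorithm"), mode = attr(report, "mode")),
    class = "linkage_eval")
}

#' @export
print.linkage_eval <- function(x, ...) {
  cat(sprintf(
    "Linkage evaluation (%s matcher, %s keys): %d records\n",
    x$algorithm, x$mode, x$m))
  cat(sprintf("  TP = %d, FP = %d, FPR = %.2f%%, accuracy = %.2f%%\n",
              x$TP, x$FP, 100 * x$FPR, 100 * x$accuracy))
  invisible(x)
}

#' @rdname evaluate_linkage
#' @param x a `linkage_eval` object.
#' @param ... unused.
#' @exportS3Method generics::glance
glance.linkage_eval <- function(x, ...) {
  tibble::tibble(algorithm = x$algorithm, mode = x$mode, n_records = x$m,
                 TP = x$TP, FP = x$FP, FPR = x$FPR, accuracy = x$accuracy)
}

#' @rdname evaluate_linkage
#' @exportS3Method generics::tidy
tidy.linkage_eval <- function(x, ...) {
  dplyr::transmute(x$per_record,
                   released_id = .data$released_id,
                   true_test_id = .data$true_test_id,
                   max_count = .data$max_count,
                   n_best = .data$n_best,
                   outcome = ifelse(.data$correct, "TP", "FP"))
}

#' @rdname link_baseline
#' @param x a `linkage_report`.
#' @param ... unused.
#' @exportS3Method generics::glance
glance.linkage_report <- function(x, ...) {
  tibble::tibble(
    algorithm = attr(x, "algorithm"), mode = attr(x, "mode"),
    n_records = attr(x, "m"), n_series = attr(x, "p"),
    n_pairs = attr(x, "n_pairs"),
    unique_best = sum(x$n_best == 1L & x$max_count > 0L),
    mean_max_count = mean(x$max_count),
    comparisons = attr(x, "ops"))
}

#' @rdname link_baseline
#' @exportS3Method generics::tidy
tidy.linkage_report <- function(x, ...) {
  tibble::as_tibble(x) |>
    tidyr::unnest_longer("matched_tests", values_to = "matched_test_id",
                         keep_empty = TRUE) |>
    dplyr::select("released_id", "max_count", "matched_test_id")
}

#' @rdname link_baseline
#' @param object a `linkage_report`.
#' @exportS3Method ggplot2::autoplot
autoplot.linkage_report <- function(object, ...) {
  df <- tibble::tibble(max_count = factor(object$max_count),
                       tied = object$n_best > 1L)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$max_count, fill = .data$tied)) +
    ggplot2::geom_bar() +
    ggplot2::labs(
      x = "shared pairs with best-matching series",
      y = "released records", fill = "tied best match",
      title = sprintf("Match-count distribution (%s keys)",
                      attr(object, "mode"))) +
    ggplot2::theme_minimal()
}
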