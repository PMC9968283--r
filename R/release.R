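#' Replace patient identifiers with fresh random pseudonyms
#'
#' Generates a bijection from the given identifiers to fresh 128-bit random
#' hex identifiers, disjoint from the input set. The map is retained by the
#' data holder and is never part of a release; it exists so identifiers
#' derived from PII (SSN, date of birth, ...) never leave the institution.
#'
#' @param patient_ids character vector of distinct identifiers.
#' @return a tibble `patient_id, subject_id` (a bijection).
#' @export
pseudonymize <- function(patient_ids) {
  if (length(patient_ids) == 0) abort("`patient_ids` must be non-empty")
  if (anyDuplicated(patient_ids)) abort("`patient_ids` must be distinct")
  n <- length(patient_ids)
  gen <- function(k) {
    hexes <- sample(c(0:9, letters[1:6]), 32 * k, replace = TRUE)
    apply(matrix(hexes, nrow = k), 1, paste0, collapse = "")
  }
  ids <- gen(n)
  # collisions (with each other or the input) are astronomically unlikely
  # at 128 bits but the bijection contract is enforced anyway
  repeat {
    bad <- duplicated(ids) | ids %in% patient_ids
    if (!any(bad)) break
    ids[bad] <- gen(sum(bad))
  }
  tibble::tibble(patient_id = patient_ids, subject_id = ids)
}

# distinct random 0-based positions per test, or fixed indices when supplied
sample_positions <- function(q, size, indices = NULL) {
  if (!is.null(indices) && length(indices) == size) return(sort(indices))
  sort(sample.int(q, size) - 1L)
}

#' Prepare a privacy-preserving release of a time-series database
#'
#' Implements the secondary-use workflow: (1) pseudonymize the study
#' patients, (2) restrict the time-series database to the study patients,
#' (3) sample a handful of (timestamp, value) pairs per test and attach
#' them to the pseudonymous subject ID, and (4) optionally verify linkage
#' robustness before release: the candidate sample table is linked back
#' against the released series with [link_sorted()] and, while any false
#' positives remain, the per-test sample size is incremented and the
#' sampling repeated. The released bundle contains no original patient
#' identifiers; the pseudonym map stays with the data holder.
#'
#' @param ergo full ERGO tibble (`test_id, reading_index, timestamp, value`).
#' @param truth tibble `test_id, patient_id` for the full database (holder's
#'   own linkage table).
#' @param study_patients character vector of patient ids to release
#'   (must all be present in `truth`).
#' @param sample_size initial number of pairs sampled per test (default 4).
#' @param indices optional fixed 0-based positions used for the first
#'   sampling attempt when their number equals `sample_size`; escalation
#'   attempts sample positions uniformly without replacement.
#' @param verify verify zero-false-positive self-linkage before release.
#' @param mode projection mode used for the verification linkage.
#' @param max_sample_size upper bound for the escalation loop (default: the
#'   series length); an error of class `tslinkage_not_robust` is raised if
#'   robustness is not reached by then.
#' @return a `release_bundle` list:
#'   `pat_release` (`subject_id, released_id, pair_index, timestamp, value`),
#'   `ergo_release` (readings of the study tests, no patient ids),
#'   `id_map` (holder-only pseudonym bijection),
#'   `sample_size_used`, and `verification` (a `linkage_eval`, or `NULL`).
#' @examples
#' cohort <- simulate_cohort(6, 2, phase_length = 30, seed = 7)
#' bundle <- prepare_release(cohort$ergo, cohort$truth,
#'                           study_patients = c("P00001", "P00002"),
#'                           sample_size = 4)
#' bundle$verification$FP  # 0
#' @export
prepare_release <- function(ergo, truth, study_patients, sample_size = 4,
                            indices = NULL, verify = TRUE,
                            mode = "datetime", max_sample_size = NULL) {
  stopifnot(is.data.frame(ergo), is.data.frame(truth))
  if (sample_size < 1) abort("`sample_size` must be >= 1")
  missing <- setdiff(study_patients, truth$patient_id)
  if (length(missing) > 0)
    abort(paste0("patients not in the database: ",
                 paste(head(missing, 5), collapse = ", ")))

  study_tests <- truth$test_id[truth$patient_id %in% study_patients]
  ergo_release <- dplyr::filter(ergo, .data$test_id %in% study_tests) |>
    dplyr::arrange(.data$test_id, .data$timestamp)
  q <- min(dplyr::count(ergo_release, .data$test_id)$n)
  if (is.null(max_sample_size)) max_sample_size <- q
  if (sample_size > q)
    abort(sprintf("sample_size %d exceeds series length %d", sample_size, q))

  id_map <- pseudonymize(unique(study_patients))
  test_subject <- truth |>
    dplyr::filter(.data$test_id %in% study_tests) |>
    dplyr::left_join(id_map, by = "patient_id")

  by_test <- dplyr::group_split(ergo_release, .data$test_id)
  size <- sample_size
  repeat {
    pat <- purrr::map(by_test, function(tt) {
      pos <- sample_positions(nrow(tt), size, indices)
      dplyr::mutate(tt[pos + 1L, ],
                    pair_index = seq_along(pos) - 1L)
    }) |> purrr::list_rbind()
    ids <- unique(pat$test_id)
    pat <- pat |>
      dplyr::transmute(
        released_id = sprintf("R%06d", match(.data$test_id, ids)),
        pair_index = .data$pair_index,
        timestamp = .data$timestamp,
        value = .data$value,
        true_test_id = .data$test_id)

    verification <- NULL
    if (verify) {
      report <- link_sorted(pat, ergo_release, mode = mode)
      verification <- evaluate_linkage(report, pat)
      if (verification$FP > 0) {
        if (size >= max_sample_size)
          abort(
            sprintf(paste0("linkage not robust at sample size %d ",
                           "(FP = %d); bound reached"),
                   size, verification$FP),
            class = "tslinkage_not_robust")
        size <- size + 1
        next
      }
    }
    break
  }

  pat_release <- pat |>
    dplyr::left_join(
      dplyr::select(test_subject, "test_id", "subject_id"),
      by = c(true_test_id = "test_id")) |>
    dplyr::select("subject_id", "released_id", "pair_index",
                  "timestamp", "value")

  structure(
    list(pat_release = pat_release, ergo_release = ergo_release,
         id_map = id_map, sample_size_used = size,
         verification = verification),
    class = "release_bundle")
}

#' @export
print.release_bundle <- function(x, ...) {
  cat(sprintf(
    paste0("Release bundle: %d series (%d readings), %d records of %d",
           " sampled pairs, %d subjects\n"),
    dplyr::n_distinct(x$ergo_release$test_id), nrow(x$ergo_release),
    dplyr::n_distinct(x$pat_release$released_id), x$sample_size_used,
    nrow(x$id_map)))
  if (!is.null(x$verification))
    cat(sprintf("  verified: FP = %d on self-linkage\n", x$verification$FP))
  invisible(x)
}
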