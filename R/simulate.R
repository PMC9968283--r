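#' Envelope parameters for one simulated ergometric test
#'
#' An ergometric (exercise) stress test produces a heart-rate series with
#' three phases — warm-up, stress and recovery — modelled here as a
#' piecewise-linear envelope: the heart rate starts at `initial_hr` and
#' accumulates the active phase's slope once per sample, with i.i.d.
#' Gaussian noise added on top.
#'
#' @param start_timestamp `POSIXct` start of the test (whole seconds).
#' @param initial_hr starting heart rate, bpm.
#' @param noise_sd standard deviation of the additive Gaussian noise, bpm
#'   (`>= 0`).
#' @param slope_warmup,slope_stress,slope_recovery average heart-rate slope
#'   in each phase, bpm per second (recovery is typically negative).
#' @return a named list of validated envelope parameters.
#' @export
envelope_params <- function(start_timestamp, initial_hr, noise_sd,
                            slope_warmup, slope_stress, slope_recovery) {
  if (!inherits(start_timestamp, "POSIXct"))
    abort("`start_timestamp` must be POSIXct")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0")
  if (initial_hr <= 0) abort("`initial_hr` must be positive")
  list(start_timestamp = start_timestamp, initial_hr = initial_hr,
       noise_sd = noise_sd, slope_warmup = slope_warmup,
       slope_stress = slope_stress, slope_recovery = slope_recovery)
}

# piecewise-linear envelope value at 0-based reading position r, given
# per-test parameters recycled along r
envelope_value <- function(r, phase_length, hr0, s1, s2, s3) {
  L <- phase_length
  hr0 +
    s1 * pmin(r, L - 1) +
    s2 * pmax(pmin(r, 2 * L - 1) - (L - 1), 0) +
    s3 * pmax(r - (2 * L - 1), 0)
}

# values are released at 1 decimal; the floor keeps extreme noise draws
# physiological
.HR_FLOOR <- 30

#' Simulate a single ergometric heart-rate test
#'
#' Generates `3 * phase_length` readings at 1 Hz starting at the envelope's
#' start timestamp. Reading values follow the three-phase piecewise-linear
#' envelope plus Gaussian noise, rounded to 1 decimal and floored at 30 bpm.
#'
#' @param envelope an [envelope_params()] list.
#' @param phase_length readings per phase (default 300, i.e. 5 minutes at
#'   1 Hz; a full test is then 900 points).
#' @return a tibble with columns `reading_index` (0-based), `timestamp`
#'   (`POSIXct`, strictly increasing at 1 s), `value` (bpm, 1 decimal).
#' @examples
#' env <- envelope_params(as.POSIXct("2020-06-01 09:00:00", tz = "UTC"),
#'                        initial_hr = 70, noise_sd = 1,
#'                        slope_warmup = 0.1, slope_stress = 0.2,
#'                        slope_recovery = -0.2)
#' test <- simulate_test(env, phase_length = 300)
#' nrow(test)  # 900
#' @export
simulate_test <- function(envelope, phase_length = 300) {
  if (length(phase_length) != 1 || is.na(phase_length) || phase_length < 1)
    abort("`phase_length` must be a positive integer")
  phase_length <- as.integer(phase_length)
  q <- 3L * phase_length
  r <- seq_len(q) - 1L
  env <- envelope_value(r, phase_length, envelope$initial_hr,
                        envelope$slope_warmup, envelope$slope_stress,
                        envelope$slope_recovery)
  v <- round(env + rnorm(q, 0, envelope$noise_sd), 1)
  tibble::tibble(
    reading_index = r,
    timestamp = envelope$start_timestamp + r,
    value = pmax(v, .HR_FLOOR)
  )
}

#' Simulate a cohort of ergometric tests
#'
#' Generates `n_patients * tests_per_patient` tests. Envelope parameters are
#' drawn independently per test, uniformly from the configured ranges. Each
#' patient's tests are scheduled sequentially with a random gap between
#' consecutive tests, so one patient's test windows never overlap; tests of
#' *different* patients may overlap in time — that overlap is what makes
#' chance collisions possible once timestamp components are dropped from the
#' match key.
#'
#' Default ranges produce warm-up/stress/recovery curves starting at
#' 60–90 bpm with 0.5–2 bpm noise, spread over a two-year window.
#'
#' @param n_patients,tests_per_patient cohort dimensions (`>= 1`).
#' @param phase_length readings per phase (default 300 -> 900 per test).
#' @param seed optional integer seed; identical configs and seeds yield
#'   bit-identical cohorts.
#' @param initial_hr,noise_sd,slope_warmup,slope_stress,slope_recovery
#'   length-2 numeric ranges `c(lo, hi)` from which per-test envelope
#'   parameters are drawn uniformly.
#' @param window length-2 `POSIXct` (or coercible) range for the first test
#'   start of each patient.
#' @param gap length-2 numeric range, seconds, for the gap between a
#'   patient's consecutive tests (default 1 hour to 7 days).
#' @return a list with components
#'   * `ergo` — tibble `test_id, reading_index, timestamp, value`, one row
#'     per reading (the full released time-series database);
#'   * `truth` — tibble `test_id, patient_id`, the ground-truth side channel
#'     (never part of a release).
#' @examples
#' cohort <- simulate_cohort(4, 2, phase_length = 30, seed = 1)
#' dplyr::n_distinct(cohort$ergo$test_id)  # 8
#' @export
simulate_cohort <- function(n_patients, tests_per_patient,
                            phase_length = 300, seed = NULL,
                            initial_hr = c(60, 90),
                            noise_sd = c(0.5, 2),
                            slope_warmup = c(0.05, 0.15),
                            slope_stress = c(0.10, 0.30),
                            slope_recovery = c(-0.30, -0.10),
                            window = c("2019-01-01", "2021-01-01"),
                            gap = c(3600, 604800)) {
  if (n_patients < 1 || tests_per_patient < 1)
    abort("`n_patients` and `tests_per_patient` must be >= 1")
  if (length(phase_length) != 1 || phase_length < 1)
    abort("`phase_length` must be a positive integer")
  if (!is.null(seed)) set.seed(seed)

  n_tests <- n_patients * tests_per_patient
  phase_length <- as.integer(phase_length)
  q <- 3L * phase_length

  patient_id <- rep(sprintf("P%05d", seq_len(n_patients)),
                    each = tests_per_patient)
  test_id <- sprintf("T%06d", seq_len(n_tests))

  hr0 <- runif(n_tests, initial_hr[1], initial_hr[2])
  sdn <- runif(n_tests, noise_sd[1], noise_sd[2])
  s1 <- runif(n_tests, slope_warmup[1], slope_warmup[2])
  s2 <- runif(n_tests, slope_stress[1], slope_stress[2])
  s3 <- runif(n_tests, slope_recovery[1], slope_recovery[2])

  window <- as.POSIXct(window, tz = "UTC")
  first_start <- floor(runif(n_patients, as.numeric(window[1]),
                             as.numeric(window[2])))
  gaps <- floor(runif(n_tests, gap[1], gap[2]))
  # sequential per-patient scheduling: each test starts after the previous
  # one ends plus a gap, so windows within a patient are disjoint
  step <- q + gaps
  idx_in_patient <- rep(seq_len(tests_per_patient), n_patients)
  cum <- stats::ave(step, rep(seq_len(n_patients), each = tests_per_patient),
                    FUN = cumsum)
  start_secs <- rep(first_start, each = tests_per_patient) + cum - step

  r <- rep(seq_len(q) - 1L, n_tests)
  tidx <- rep(seq_len(n_tests), each = q)
  env <- envelope_value(r, phase_length, hr0[tidx], s1[tidx], s2[tidx],
                        s3[tidx])
  value <- pmax(round(env + rnorm(length(r), 0, sdn[tidx]), 1), .HR_FLOOR)

  ergo <- tibble::tibble(
    test_id = rep(test_id, each = q),
    reading_index = r,
    timestamp = as.POSIXct(start_secs[tidx] + r,
                           origin = "1970-01-01", tz = "UTC"),
    value = value
  )
  truth <- tibble::tibble(test_id = test_id, patient_id = patient_id)
  list(ergo = ergo, truth = truth)
}

#' Sample a minimal identifying release (PAT table) from an ERGO table
#'
#' Projects each test down to the readings at the given 0-based positions —
#' the released quasi-identifier-free record. With the default indices the
#' four readings are the start of the test and the end of each phase of a
#' 900-point test.
#'
#' @param ergo an ERGO tibble (`test_id, reading_index, timestamp, value`).
#' @param indices 0-based positions within each test's time-ordered readings
#'   (default `c(0, 299, 599, 899)`).
#' @param keep_truth keep the source `test_id` as a `true_test_id` column
#'   (ground truth for evaluation; drop for an actual release).
#' @return a PAT tibble `released_id, pair_index, timestamp, value`
#'   (+ `true_test_id`), with one record of `length(indices)` pairs per test.
#' @export
sample_pat <- function(ergo, indices = c(0, 299, 599, 899),
                       keep_truth = TRUE) {
  stopifnot(is.data.frame(ergo))
  indices <- as.integer(indices)
  if (anyNA(indices) || any(indices < 0)) abort("indices must be >= 0")
  if (anyDuplicated(indices)) abort("indices must be distinct")

  ergo <- dplyr::arrange(ergo, .data$test_id, .data$timestamp)
  sizes <- dplyr::count(ergo, .data$test_id)
  qmin <- min(sizes$n)
  if (any(indices >= qmin)) {
    bad <- indices[indices >= qmin][1]
    abort(sprintf("index %d out of range: shortest test has %d readings",
                  bad, qmin))
  }
  pat <- ergo |>
    dplyr::group_by(.data$test_id) |>
    dplyr::slice(indices + 1L) |>
    dplyr::mutate(pair_index = seq_along(.data$value) - 1L) |>
    dplyr::ungroup()
  ids <- unique(pat$test_id)
  pat |>
    dplyr::transmute(
      released_id = sprintf("R%06d", match(.data$test_id, ids)),
      pair_index = .data$pair_index,
      timestamp = .data$timestamp,
      value = .data$value,
      true_test_id = .data$test_id
    ) |>
    (\(x) if (keep_truth) x else dplyr::select(x, -"true_test_id"))()
}
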