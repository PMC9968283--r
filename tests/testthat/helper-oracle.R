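# Independent pure-R oracle for match counting: nested membership, no
# sorting, no C++. Counts, for every (PAT record, ERGO row) pair, how many
# of the record's keys occur in the row (each pair contributes at most 1).
nested_membership_counts <- function(pat, ergo, mode = "datetime") {
  pat_ids <- unique(pat$released_id)
  ergo_ids <- unique(ergo$test_id)
  pkey <- split(project_key(pat$timestamp, pat$value, mode),
                factor(pat$released_id, levels = pat_ids))
  ekey <- split(project_key(ergo$timestamp, ergo$value, mode),
                factor(ergo$test_id, levels = ergo_ids))
  out <- list()
  for (i in seq_along(pkey)) {
    for (k in seq_along(ekey)) {
      cnt <- sum(pkey[[i]] %in% ekey[[k]])
      if (cnt > 0)
        out[[length(out) + 1]] <- c(i = i, k = k, count = cnt)
    }
  }
  if (length(out) == 0)
    return(tibble::tibble(pat_row = integer(), ergo_row = integer(),
                          count = integer()))
  m <- do.call(rbind, out)
  tibble::tibble(pat_row = as.integer(m[, "i"]),
                 ergo_row = as.integer(m[, "k"]),
                 count = as.integer(m[, "count"])) |>
    dplyr::arrange(pat_row, ergo_row)
}

# Report derived from the oracle counts: per record, max count and all rows
# attaining it (empty set when nothing matches).
oracle_report <- function(pat, ergo, mode = "datetime") {
  pat_ids <- unique(pat$released_id)
  ergo_ids <- unique(ergo$test_id)
  counts <- nested_membership_counts(pat, ergo, mode)
  max_count <- integer(length(pat_ids))
  matched <- rep(list(character(0)), length(pat_ids))
  for (i in seq_along(pat_ids)) {
    sub <- counts[counts$pat_row == i, ]
    if (nrow(sub) > 0) {
      max_count[i] <- max(sub$count)
      matched[[i]] <- ergo_ids[sort(sub$ergo_row[sub$count == max_count[i]])]
    }
  }
  tibble::tibble(released_id = pat_ids, max_count = max_count,
                 n_best = lengths(matched), matched_tests = matched)
}

# strip matcher metadata so reports from different routes compare equal
strip_report <- function(report) {
  out <- tibble::tibble(released_id = report$released_id,
                        max_count = as.integer(report$max_count),
                        n_best = as.integer(report$n_best),
                        matched_tests = report$matched_tests)
  out$matched_tests <- lapply(out$matched_tests, as.character)
  out
}

# Random small instance with engineered key collisions: timestamps drawn
# from a small pool of seconds and values from a coarse grid, so every
# projection mode produces genuine ties and partial matches.
random_instance <- function(seed, m_max = 8, p_max = 8, q_max = 12,
                            n_pairs = 3) {
  set.seed(seed)
  m <- sample(2:m_max, 1)
  p <- sample(2:p_max, 1)
  q <- sample(4:q_max, 1)
  base <- as.POSIXct("2020-05-01 08:00:00", tz = "UTC")
  ts_pool <- base + sample(0:5, 40, replace = TRUE) * 86400 +
    sample(0:3, 40, replace = TRUE) * 3600 + sample(0:2, 40, replace = TRUE)
  val_pool <- seq(60, 75, by = 0.5)
  ergo <- tibble::tibble(
    test_id = rep(sprintf("E%02d", seq_len(p)), each = q),
    reading_index = rep(seq_len(q) - 1L, p),
    timestamp = sample(ts_pool, p * q, replace = TRUE),
    value = sample(val_pool, p * q, replace = TRUE))
  pat <- tibble::tibble(
    released_id = rep(sprintf("R%02d", seq_len(m)), each = n_pairs),
    pair_index = rep(seq_len(n_pairs) - 1L, m),
    timestamp = sample(ts_pool, m * n_pairs, replace = TRUE),
    value = sample(val_pool, m * n_pairs, replace = TRUE))
  # splice some verbatim ergo pairs into PAT so strong partial matches exist
  take <- sample(nrow(ergo), min(nrow(pat), nrow(ergo)) %/% 2)
  rows <- sample(nrow(pat), length(take))
  pat$timestamp[rows] <- ergo$timestamp[take]
  pat$value[rows] <- ergo$value[take]
  list(pat = pat, ergo = ergo)
}

# toy cohort shared by several tests
toy_cohort <- function(n_patients = 5, tests_per_patient = 2,
                       phase_length = 30, seed = 42) {
  simulate_cohort(n_patients, tests_per_patient,
                  phase_length = phase_length, seed = seed)
}
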