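base_ts <- as.POSIXct("2020-05-01 08:00:00", tz = "UTC")

# small hand-built instance: ergo rows E01..E05 of 3 readings each
hand_ergo <- tibble::tibble(
  test_id = rep(sprintf("E%02d", 1:5), each = 3),
  reading_index = rep(0:2, 5),
  timestamp = base_ts + seq_len(15),
  value = 60 + seq_len(15) / 10)

test_that("a record sharing 2 pairs with two rows ties between them", {
  # PAT record takes one reading from E02, one from E04 -> count 1 each;
  # a second record takes two readings from E03 -> unique best match
  pat <- tibble::tibble(
    released_id = c("R01", "R01", "R02", "R02"),
    pair_index = c(0L, 1L, 0L, 1L),
    timestamp = hand_ergo$timestamp[c(4, 10, 7, 8)],
    value = hand_ergo$value[c(4, 10, 7, 8)])
  for (linker in list(link_baseline, link_sorted)) {
    rep <- linker(pat, hand_ergo)
    expect_equal(rep$max_count, c(1L, 2L))
    expect_equal(rep$matched_tests[[1]], c("E02", "E04"))
    expect_equal(rep$matched_tests[[2]], "E03")
  }
  # brute-force enumeration agrees
  expect_equal(strip_report(link_baseline(pat, hand_ergo)),
               strip_report(oracle_report(pat, hand_ergo)))
})

test_that("verbatim-sampled records match their true test with count n", {
  cohort <- toy_cohort()
  pat <- sample_pat(cohort$ergo, indices = c(0, 29, 59, 89))
  for (linker in list(link_baseline, link_sorted)) {
    rep <- linker(pat, cohort$ergo)
    expect_true(all(rep$max_count == 4L))
    expect_equal(unlist(rep$matched_tests),
                 unique(pat$true_test_id))
  }
  # count(i, true_row) = n, via the exposed merge path
  seqs <- build_tagged_sequences(pat, cohort$ergo)
  s1 <- dplyr::arrange(seqs$s1, key, row)
  s2 <- dplyr::arrange(seqs$s2, key, row)
  counts <- merge_count(s1, s2)
  true_rows <- match(unique(pat$true_test_id), seqs$ergo_ids)
  diag <- dplyr::semi_join(
    counts,
    tibble::tibble(pat_row = seq_along(true_rows), ergo_row = true_rows),
    by = c("pat_row", "ergo_row"))
  expect_true(all(diag$count == 4L))
})

test_that("merge_count matches hand enumeration and enforces sortedness", {
  s1 <- tibble::tibble(key = 5, row = 1L)
  s2 <- tibble::tibble(key = c(5, 5), row = c(1L, 2L))
  out <- merge_count(s1, s2)
  expect_equal(out$pat_row, c(1L, 1L))
  expect_equal(out$ergo_row, c(1L, 2L))
  expect_equal(out$count, c(1L, 1L))

  disjoint <- merge_count(tibble::tibble(key = 1, row = 1L),
                          tibble::tibble(key = 2, row = 1L))
  expect_equal(nrow(disjoint), 0)

  unsorted <- tibble::tibble(key = c(2, 1), row = c(1L, 1L))
  expect_error(merge_count(unsorted, s2), "sorted")
})

test_that("tagged sequences have mn elements and de-duplicate ergo rows", {
  pat <- tibble::tibble(
    released_id = rep(c("R01", "R02"), each = 4),
    pair_index = rep(0:3, 2),
    timestamp = base_ts + 1:8, value = rep(61, 8))
  # one ergo row whose readings collapse to one key under date_only
  ergo <- tibble::tibble(
    test_id = "E01", reading_index = 0:3,
    timestamp = base_ts + c(1, 2, 3, 90000), value = rep(61, 4))
  seqs <- build_tagged_sequences(pat, ergo, "date_only")
  expect_equal(nrow(seqs$s1), 2 * 4)
  expect_equal(nrow(seqs$s2), 2)  # two distinct dates remain
  # tags are independent of the key transform
  seqs_dt <- build_tagged_sequences(pat, ergo, "datetime")
  expect_equal(sort(unique(seqs_dt$s1$row)), sort(unique(seqs$s1$row)))

  # de-duplication gives membership semantics: repeated key in a row still
  # contributes 1
  rep <- link_sorted(pat, ergo, "date_only")
  expect_equal(rep$max_count, c(4L, 4L))
})

test_that("both matchers and merge counting agree with the nested oracle
           on randomized instances", {
  for (s in 1:40) {
    inst <- random_instance(1000 + s)
    mode <- c("datetime", "date_only", "time_only", "value_only")[
      1 + (s %% 4)]
    want <- oracle_report(inst$pat, inst$ergo, mode)
    expect_equal(strip_report(link_baseline(inst$pat, inst$ergo, mode)),
                 strip_report(want))
    expect_equal(strip_report(link_sorted(inst$pat, inst$ergo, mode)),
                 strip_report(want))
    seqs <- build_tagged_sequences(inst$pat, inst$ergo, mode)
    counts <- merge_count(dplyr::arrange(seqs$s1, key, row),
                          dplyr::arrange(seqs$s2, key, row))
    expect_equal(
      tibble::tibble(pat_row = counts$pat_row, ergo_row = counts$ergo_row,
                     count = as.integer(counts$count)),
      nested_membership_counts(inst$pat, inst$ergo, mode))
  }
})

test_that("coarsening the key never decreases any count", {
  chains <- list(c("datetime", "date_only", "value_only"),
                 c("datetime", "time_only", "value_only"))
  for (s in 1:10) {
    inst <- random_instance(2000 + s)
    for (chain in chains) {
      prev <- NULL
      for (mode in chain) {
        seqs <- build_tagged_sequences(inst$pat, inst$ergo, mode)
        counts <- merge_count(dplyr::arrange(seqs$s1, key, row),
                              dplyr::arrange(seqs$s2, key, row))
        n <- max(tabulate(seqs$s1$row))
        expect_true(all(counts$count >= 1 & counts$count <= n))
        if (!is.null(prev)) {
          j <- dplyr::left_join(prev, counts,
                                by = c("pat_row", "ergo_row"),
                                suffix = c("_fine", "_coarse"))
          expect_true(all(j$count_coarse >= j$count_fine))
        }
        prev <- counts
      }
    }
  }
})

test_that("degenerate inputs follow the declared conventions", {
  empty <- hand_ergo[0, ]
  pat <- tibble::tibble(released_id = "R01", pair_index = 0L,
                        timestamp = base_ts, value = 61)
  expect_error(link_sorted(pat, empty), "empty")
  expect_error(link_baseline(pat[0, ], hand_ergo), "empty")

  # a record matching nothing has an empty argmax set, not "all rows"
  nowhere <- tibble::tibble(released_id = "R01", pair_index = 0L,
                            timestamp = base_ts - 999, value = 42.1)
  for (linker in list(link_baseline, link_sorted)) {
    rep <- linker(nowhere, hand_ergo)
    expect_equal(rep$max_count, 0L)
    expect_equal(rep$n_best, 0L)
    expect_length(rep$matched_tests[[1]], 0)
  }
})

test_that("evaluation counts ties, misses and empty sets as FP", {
  cohort <- toy_cohort()
  pat <- sample_pat(cohort$ergo, indices = c(0, 29, 59, 89))
  ev <- evaluate_linkage(link_sorted(pat, cohort$ergo), pat)
  expect_equal(ev$TP, 10)
  expect_equal(ev$FP, 0)
  expect_equal(ev$accuracy, 1)

  # duplicate one test's readings into an impostor -> that record ties
  dup <- cohort$ergo |>
    dplyr::filter(test_id == "T000001") |>
    dplyr::mutate(test_id = "T999999")
  ergo2 <- dplyr::bind_rows(cohort$ergo, dup)
  ev2 <- evaluate_linkage(link_sorted(pat, ergo2), pat)
  expect_equal(ev2$TP, 9)
  expect_equal(ev2$FP, 1)
  expect_equal(ev2$FPR, 0.1)
  expect_equal(ev2$TP + ev2$FP, ev2$m)
  expect_equal(ev2$FPR + ev2$accuracy, 1)

  # a report with no matches anywhere: TP = 0, FP = m
  off <- dplyr::mutate(pat, value = value + 500)
  ev3 <- evaluate_linkage(link_sorted(off, cohort$ergo), pat |>
                            dplyr::select(released_id, true_test_id))
  expect_equal(ev3$TP, 0)
  expect_equal(ev3$FP, ev3$m)

  # missing truth entries are reported by record
  expect_error(evaluate_linkage(link_sorted(pat, cohort$ergo),
                                pat[pat$released_id != "R000003", ]),
               "R000003")
})

test_that("reports expose tidy, glance and autoplot views", {
  cohort <- toy_cohort()
  pat <- sample_pat(cohort$ergo, indices = c(0, 29, 59, 89))
  rep <- link_sorted(pat, cohort$ergo)
  td <- tidy(rep)
  expect_equal(nrow(td), 10)
  expect_named(td, c("released_id", "max_count", "matched_test_id"))
  gl <- glance(rep)
  expect_equal(gl$unique_best, 10)
  expect_true(gl$comparisons > 0)
  expect_s3_class(autoplot(rep), "ggplot")

  ev <- evaluate_linkage(rep, pat)
  expect_equal(glance(ev)$accuracy, 1)
  expect_equal(sort(unique(tidy(ev)$outcome)), "TP")
  expect_output(print(ev), "accuracy = 100.00%")
})
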