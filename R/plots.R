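#' Plot simulated heart-rate curves
#'
#' Draws a sample of tests from an ERGO table, one panel per test, to eyeball
#' the three-phase warm-up / stress / recovery envelope and the noise level.
#'
#' @param ergo an ERGO tibble.
#' @param n_tests number of tests to draw (sampled in table order).
#' @return a ggplot object.
#' @export
plot_heart_rate <- function(ergo, n_tests = 6) {
  ids <- head(unique(ergo$test_id), n_tests)
  df <- dplyr::filter(ergo, .data$test_id %in% ids) |>
    dplyr::group_by(.data$test_id) |>
    dplyr::mutate(elapsed_min = (dplyr::row_number() - 1) / 60) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$elapsed_min, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "#2c7fb8") +
    ggplot2::facet_wrap(~test_id, scales = "free") +
    ggplot2::labs(x = "elapsed time (min)", y = "heart rate (bpm)",
                  title = "Simulated ergometric tests") +
    ggplot2::theme_minimal()
}
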