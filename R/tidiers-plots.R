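#' @exportS3Method
tidy.delta_frequency_result <- function(x, ...) {
  x$deltas |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      median_delta = stats::median(.data$delta, na.rm = TRUE),
      mean_delta = mean(.data$delta, na.rm = TRUE),
      q025 = quantile(.data$delta, 0.025, na.rm = TRUE),
      q975 = quantile(.data$delta, 0.975, na.rm = TRUE),
      .groups = "drop") |>
    dplyr::left_join(x$binning$bins, by = "bin") |>
    dplyr::relocate("bin", "n", "age_min", "age_max")
}

#' @exportS3Method
glance.delta_frequency_result <- function(x, ...) {
  out <- tibble(n_focal = x$n_focal, n_neutral = x$n_neutral,
                n_bins = x$binning$n_bins, reps = x$reps)
  if (!is.null(x$pattern_reproduced)) {
    out$pattern_reproduced <- x$pattern_reproduced
    out$n_bins_below_zero <- sum(x$below_zero$significant)
  }
  out
}

#' Boxplot of the age-adjusted SFS
#'
#' One box per age bin over the resampled delta-frequency estimates, bins
#' labelled by their age range, youngest to oldest; the dashed line marks
#' the neutral expectation delta = 0.
#'
#' @param object a `delta_frequency_result`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.delta_frequency_result <- function(object, ...) {
  lab <- object$binning$bins |>
    dplyr::mutate(label = sprintf("%.0f-%.0f", .data$age_min, .data$age_max))
  d <- dplyr::left_join(object$deltas, lab, by = "bin")
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$label, .data$bin), y = .data$delta)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.7, outlier.size = 0.5) +
    ggplot2::labs(x = "allele age range (generations)",
                  y = expression(Delta ~ "frequency"),
                  title = "Age-adjusted SFS") +
    ggplot2::theme_minimal()
}

#' Bar chart of relative age differences across the selection grid
#'
#' Mirrors the grid-matching view: one panel per age quantile, one bar per
#' simulated selection strength; the best-fitting S minimizes the absolute
#' relative age difference.
#'
#' @param object a `selection_estimate`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.selection_estimate <- function(object, ...) {
  d <- object$table |>
    dplyr::mutate(quantile = factor(paste0(100 * .data$quantile, "% quantile")))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$S), y = .data$rel_age_diff)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_col(fill = "firebrick", alpha = 0.8) +
    ggplot2::facet_wrap(~quantile) +
    ggplot2::labs(x = "scaled selection coefficient S",
                  y = "relative age difference (sim - obs)") +
    ggplot2::theme_minimal()
}

#' Plot a folded site frequency spectrum
#'
#' @param sfs a [folded_sfs()] tibble.
#' @return A ggplot object.
#' @export
plot_folded_sfs <- function(sfs) {
  d <- dplyr::mutate(sfs, label = sprintf("(%.2f, %.2f]", .data$lower, .data$upper))
  ggplot2::ggplot(d, ggplot2::aes(
    x = stats::reorder(.data$label, .data$lower), y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "minor allele frequency", y = "segregating sites",
                  title = "Folded SFS") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the allele age-frequency sanity check
#'
#' Observed mean ages per frequency bin against the neutral Kimura-Ohta
#' expectation.
#'
#' @param object an `age_sanity_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @exportS3Method
autoplot.age_sanity_report <- function(object, ...) {
  d <- tidyr::pivot_longer(object$table,
                           c("mean_age_observed", "mean_age_expected"),
                           names_to = "which", values_to = "age")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_freq, y = .data$age,
                                  colour = .data$which)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(
      values = c(mean_age_observed = "steelblue", mean_age_expected = "grey30"),
      labels = c(mean_age_observed = "observed", mean_age_expected = "neutral theory")) +
    ggplot2::labs(x = "derived allele frequency", y = "mean allele age (generations)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
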