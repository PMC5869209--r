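#' Plot PCoA coordinates
#'
#' Scatter of the first two principal coordinates, optionally coloured by a
#' sample grouping (join `data` by `sample_id`).
#'
#' @param object A `kiwi_pcoa` object.
#' @param data Optional sample metadata tibble with `sample_id`.
#' @param colour Column of `data` mapped to colour (default `species` when
#'   present).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kiwi_pcoa <- function(object, data = NULL, colour = "species", ...) {
  d <- object$coordinates
  aes_args <- ggplot2::aes(x = .data$axis_1, y = .data$axis_2)
  if (!is.null(data)) {
    d <- dplyr::left_join(d, dplyr::distinct(data, .data$sample_id,
                                             .keep_all = TRUE),
                          by = "sample_id")
    if (colour %in% names(d)) {
      aes_args <- ggplot2::aes(x = .data$axis_1, y = .data$axis_2,
                               colour = .data[[colour]])
    }
  }
  ggplot2::ggplot(d, aes_args) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("Coordinate 1 (%.1f%%)", object$pct_variance[1]),
      y = sprintf("Coordinate 2 (%.1f%%)",
                  ifelse(length(object$pct_variance) > 1,
                         object$pct_variance[2], NA)),
      colour = colour
    ) +
    ggplot2::theme_minimal()
}

#' Plot a fitted standard curve
#'
#' Standard wells with the fitted Cq-on-log10(concentration) line.
#'
#' @param object A `kiwi_std_curve` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kiwi_std_curve <- function(object, ...) {
  d <- tibble::tibble(lx = object$model$model$lx, cq = object$model$model$cq)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$lx, y = .data$cq)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$slope, linetype = 2) +
    ggplot2::labs(
      x = "log10 concentration",
      y = "Cq",
      title = sprintf("Efficiency %.2f, R2 = %.4f", object$efficiency,
                      object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Plot cumulative probability of identity
#'
#' PI and PIsibs against the number of loci combined, per population, on a
#' log scale.
#'
#' @param cum_pi Tibble from [cumulative_pi()].
#' @param grouping Population grouping column.
#' @return A ggplot object.
#' @export
plot_cumulative_pi <- function(cum_pi, grouping = "population") {
  d <- cum_pi |>
    tidyr::pivot_longer(c("pi_cum", "pisibs_cum"), names_to = "statistic",
                        values_to = "value") |>
    dplyr::mutate(statistic = dplyr::recode(.data$statistic,
                                            pi_cum = "PI",
                                            pisibs_cum = "PIsibs"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$k, y = .data$value,
                                  colour = .data[[grouping]],
                                  linetype = .data$statistic)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Loci combined", y = "Probability of identity") +
    ggplot2::theme_minimal()
}

#' Plot per-sample QI distribution
#'
#' Histogram of per-sample QI with the success threshold marked.
#'
#' @param sample_qi Tibble from [qi_by_sample()].
#' @param threshold Success threshold to mark.
#' @return A ggplot object.
#' @export
plot_qi <- function(sample_qi, threshold = 0.75) {
  ggplot2::ggplot(sample_qi, ggplot2::aes(x = .data$qi)) +
    ggplot2::geom_histogram(binwidth = 0.05, boundary = 0) +
    ggplot2::geom_vline(xintercept = threshold, linetype = 2) +
    ggplot2::labs(x = "Quality index (QI)", y = "Samples") +
    ggplot2::theme_minimal()
}
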