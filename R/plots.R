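# ggplot2 displays for the main result types.

#' @describeIn ccc_profile Plot the cross-context correlation against the
#'   noise ceiling, one panel per segment duration.
#' @param object A `tci_ccc_profile` tibble.
#' @param ... Unused.
#' @method autoplot tci_ccc_profile
#' @export
autoplot.tci_ccc_profile <- function(object, ...) {
  dat <- object %>%
    tidyr::pivot_longer(c("ccc", "ceiling"), names_to = "curve") %>%
    mutate(
      duration_ms = factor(
        sprintf("%s ms", fmt_ms(.data$duration)),
        levels = sprintf("%s ms", fmt_ms(sort(unique(.data$duration))))
      )
    )
  ggplot2::ggplot(
    dat,
    ggplot2::aes(.data$lag * 1000, .data$value,
      colour = .data$curve, linetype = .data$curve
    )
  ) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~duration_ms, scales = "free_x") +
    ggplot2::scale_colour_manual(values = c(ccc = "#2166ac", ceiling = "grey30")) +
    ggplot2::labs(
      x = "lag re segment onset (ms)", y = "correlation",
      colour = NULL, linetype = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn fit_window Plot observed cross-context correlation, noise
#'   ceiling and the fitted window's prediction per duration.
#' @param object A `tci_window_fit`.
#' @method autoplot tci_window_fit
#' @export
autoplot.tci_window_fit <- function(object, ...) {
  dat <- object$predictions %>%
    tidyr::pivot_longer(c("ccc", "ceiling", "predicted"), names_to = "curve") %>%
    mutate(
      duration_ms = factor(
        sprintf("%s ms", fmt_ms(.data$duration)),
        levels = sprintf("%s ms", fmt_ms(sort(unique(.data$duration))))
      )
    )
  ggplot2::ggplot(
    dat,
    ggplot2::aes(.data$lag * 1000, .data$value, colour = .data$curve)
  ) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~duration_ms, scales = "free_x") +
    ggplot2::scale_colour_manual(
      values = c(ccc = "#2166ac", ceiling = "grey30", predicted = "#b2182b")
    ) +
    ggplot2::labs(
      x = "lag re segment onset (ms)", y = "correlation",
      colour = NULL,
      title = sprintf(
        "width %.3g ms, center %.3g ms, shape %d",
        object$width * 1000, object$center * 1000, object$shape
      )
    ) +
    ggplot2::theme_minimal()
}

#' Histogram of fitted integration-window widths
#'
#' @param fits A [fit_study()] table (or any tibble with `width`,
#'   optionally a grouping column).
#' @param by Optional name of a grouping column (e.g. `"group"`).
#' @param bins Number of histogram bins (log-width axis).
#' @return A ggplot object.
#' @export
plot_width_histogram <- function(fits, by = NULL, bins = 15) {
  p <- ggplot2::ggplot(fits, ggplot2::aes(.data$width * 1000))
  p <- if (is.null(by)) {
    p + ggplot2::geom_histogram(bins = bins, fill = "#2166ac", colour = "white")
  } else {
    p + ggplot2::geom_histogram(
      ggplot2::aes(fill = .data[[by]]),
      bins = bins, position = "identity", alpha = 0.6, colour = "white"
    )
  }
  p +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "integration width (ms)", y = "units", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot group-level normalized cross-context correlation
#'
#' @param normalized A [group_normalized_ccc()] table.
#' @param by Optional grouping column name mapped to colour.
#' @return A ggplot object.
#' @export
plot_group_ccc <- function(normalized, by = NULL) {
  aes <- if (is.null(by)) {
    ggplot2::aes(.data$lag * 1000, .data$normalized)
  } else {
    ggplot2::aes(.data$lag * 1000, .data$normalized, colour = .data[[by]])
  }
  ggplot2::ggplot(normalized, aes) +
    ggplot2::geom_hline(yintercept = c(0, 1), colour = "grey70") +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~ sprintf("%s ms", fmt_ms(duration)), scales = "free_x") +
    ggplot2::labs(
      x = "lag re segment onset (ms)",
      y = "CCC / noise ceiling", colour = NULL
    ) +
    ggplot2::theme_minimal()
}
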