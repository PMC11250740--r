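# ggplot2 methods for the main result types.

#' @export
autoplot.psd_result <- function(object, measure = c("relative", "absolute"),
                                ...) {
  measure <- match.arg(measure)
  ggplot2::ggplot(object$spectrum,
                  ggplot2::aes(x = .data$freq, y = .data[[measure]])) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Frequency (Hz)",
      y = if (measure == "relative") "Relative PSD" else "PSD",
      title = sprintf("Multitaper PSD (%d segments, nw = %g, %d tapers)",
                      object$n_segments, object$nw, object$k)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.gpdc_spectrum <- function(object, ...) {
  tbl <- object$table[object$table$target != object$table$source, ]
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$freq, y = .data$gpdc)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~direction) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Frequency (Hz)", y = "gPDC",
                  title = "Generalized partial directed coherence") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.pointwise_test <- function(object, ...) {
  tbl <- tidyr::pivot_longer(object$table, c("mean_a", "mean_b"),
                             names_to = "group", values_to = "mean")
  p <- ggplot2::ggplot(tbl, ggplot2::aes(x = .data$freq, y = .data$mean,
                                         colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)", y = "Group mean",
                  title = sprintf("Point-by-point comparison (BH-FDR q = %g)",
                                  object$q)) +
    ggplot2::theme_minimal()
  if (nrow(object$intervals)) {
    p <- p + ggplot2::geom_rect(
      data = object$intervals,
      ggplot2::aes(xmin = .data$lo, xmax = .data$hi, ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.15, fill = "red"
    )
  }
  p
}

#' @export
autoplot.trial_tensor <- function(object, ...) {
  tbl <- tidy(object)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$bin_start, y = .data$trial,
                                    fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Time from stimulus onset (s)", y = "Trial",
                  fill = "Rate (Hz)") +
    ggplot2::theme_minimal()
}

#' Z-scored PSTH line plot
#'
#' @param z A [zscore_psth()] tibble.
#' @return A ggplot.
#' @export
plot_zscore_psth <- function(z) {
  ggplot2::ggplot(z, ggplot2::aes(x = .data$bin_start, y = .data$z)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Time from stimulus onset (s)", y = "Z score") +
    ggplot2::theme_minimal()
}
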