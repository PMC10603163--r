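#' Plot a degree CCDF with fitted tail models
#'
#' Log–log CCDF of the degree sequence; fitted power-law and exponential
#' tails, rescaled to the empirical CCDF at their cutoff, are overlaid when
#' supplied.
#'
#' @param degrees Degree sequence.
#' @param fits Optional list of `tail_fit` objects to overlay.
#' @return A ggplot object.
#' @export
plot_ccdf <- function(degrees, fits = NULL) {
  cc <- ccdf(degrees)
  p <- ggplot2::ggplot(cc, ggplot2::aes(x = .data$k, y = .data$p)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree k", y = "P(K ≥ k)") +
    ggplot2::theme_minimal()
  for (f in fits %||% list()) {
    anchor <- cc$p[findInterval(f$k_min, cc$k)]
    ks <- exp(seq(log(f$k_min), log(max(cc$k)), length.out = 100))
    if (f$domain == "discrete") ks <- unique(round(ks))
    line <- tibble(k = ks, p = anchor * tail_ccdf_model(f, ks), family = f$family)
    p <- p + ggplot2::geom_line(
      data = line,
      ggplot2::aes(x = .data$k, y = .data$p, linetype = .data$family)
    )
  }
  p
}

#' Plot the log-mass histogram with detected modes
#'
#' @param histogram Output of [log_mass_histogram()] (optionally stratified).
#' @param summary Optional [detect_modes_troughs()] result; detected mode
#'   centres are marked with vertical lines.
#' @return A ggplot object.
#' @export
plot_mass_histogram <- function(histogram, summary = NULL) {
  h <- mutate(histogram, center = sqrt(.data$bin_low_da * .data$bin_high_da))
  aes <- if ("stratum" %in% names(h)) {
    ggplot2::aes(x = .data$center, y = .data$count, fill = .data$stratum)
  } else {
    ggplot2::aes(x = .data$center, y = .data$count)
  }
  p <- ggplot2::ggplot(h, aes) +
    ggplot2::geom_col(width = 0.2 * h$center) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "molecular mass (Da)", y = "compounds per bin") +
    ggplot2::theme_minimal()
  if (!is.null(summary) && nrow(summary$modes)) {
    p <- p + ggplot2::geom_vline(xintercept = summary$modes$center_mass_da,
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot 2D embedding coordinates
#'
#' @param coords Tibble from [reduce_2d()].
#' @param labels Optional label per node (layer or module) used for colour.
#' @return A ggplot object.
#' @export
plot_embedding <- function(coords, labels = NULL) {
  d <- coords
  if (!is.null(labels)) d$label <- as.character(labels)
  aes <- if (is.null(labels)) {
    ggplot2::aes(x = .data$x, y = .data$y)
  } else {
    ggplot2::aes(x = .data$x, y = .data$y, colour = .data$label)
  }
  ggplot2::ggplot(d, aes) +
    ggplot2::geom_point(size = 0.7, alpha = 0.7) +
    ggplot2::labs(x = "component 1", y = "component 2") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.mass_mode_summary <- function(object, histogram, ...) {
  plot_mass_histogram(histogram, object)
}
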