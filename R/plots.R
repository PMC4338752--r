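#' Plot an activation map
#'
#' Electrode scatter in the shared coordinate frame with activation index
#' as marker size and colour (zero-AI electrodes drawn hollow). Works for
#' single-subject maps and pooled maps.
#'
#' @param object An `activation_map` or `pooled_activation_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot activation_map
#' @export
autoplot.activation_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(
      data = function(d) d[!d$significant, ],
      shape = 1, size = 2, colour = "grey60"
    ) +
    ggplot2::geom_point(
      data = function(d) d[d$significant, ],
      ggplot2::aes(size = .data$ai, colour = .data$ai)
    ) +
    ggplot2::scale_colour_viridis_c(name = "AI") +
    ggplot2::scale_size_continuous(name = "AI", range = c(2, 6)) +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~dimension) +
    ggplot2::labs(
      x = "x (mm)", y = "y (mm)",
      title = "Activation map (gamma-band discrimination)"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.activation_map
#' @method autoplot pooled_activation_map
#' @export
autoplot.pooled_activation_map <- autoplot.activation_map

#' Plot a temporal activation profile
#'
#' Mean activation index across electrodes against latency relative to
#' phoneme onset, with the peak and local maxima marked.
#'
#' @param object A `temporal_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot temporal_profile
#' @export
autoplot.temporal_profile <- function(object, ...) {
  prof <- object$profile
  p <- ggplot2::ggplot(prof, ggplot2::aes(x = .data$latency_ms, y = .data$ai)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::annotate(
      "point",
      x = object$peak_latency_ms, y = object$peak_ai,
      colour = "red", size = 2
    ) +
    ggplot2::labs(
      x = "Latency relative to phoneme onset (ms)",
      y = "Activation index",
      title = paste0("Temporal profile: ", object$dimension)
    ) +
    ggplot2::theme_minimal()
  if (length(object$local_maxima)) {
    p <- p + ggplot2::geom_vline(
      xintercept = object$local_maxima, linetype = "dashed", colour = "grey50"
    )
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
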