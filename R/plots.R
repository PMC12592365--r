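#' Plot trait-level thriving curves
#'
#' One panel of posterior-mean psi(T) curves with 95% credible ribbons,
#' faceted (or coloured) by trait.
#'
#' @param curves Row-bound `trait_curve` tibble.
#' @param facet Facet by trait instead of overlaying colours.
#' @return A ggplot object.
#' @export
plot_trait_curves <- function(curves, facet = TRUE) {
  p <- ggplot2::ggplot(
    curves,
    ggplot2::aes(x = .data$temperature, y = .data$psi_mean)
  ) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(
      x = "Temperature (°C)", y = "Probability of thriving ψ"
    ) +
    ggplot2::theme_minimal()
  if (facet) {
    p +
      ggplot2::geom_ribbon(
        ggplot2::aes(ymin = .data$psi_lo, ymax = .data$psi_hi),
        fill = "steelblue", alpha = 0.25
      ) +
      ggplot2::geom_line(colour = "steelblue") +
      ggplot2::facet_wrap(~trait_id)
  } else {
    p + ggplot2::geom_line(ggplot2::aes(colour = .data$trait_id))
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the integrated thermal performance curve
#'
#' The fitted beta-GAM curve with its 95% band, the classification
#' threshold, and hotspot/occasional shading.
#'
#' @param object An `integrated_curve`.
#' @param classification Optional `habitat_classification` for shading.
#' @param threshold Threshold line (taken from `classification` if given).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.integrated_curve <- function(object, classification = NULL,
                                      threshold = 0.5, ...) {
  df <- object$curve
  if (!is.null(classification)) threshold <- classification$threshold
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$temperature, y = .data$psi_fit))
  if (!is.null(classification)) {
    iv <- classification$intervals
    p <- p + ggplot2::geom_rect(
      data = iv,
      ggplot2::aes(
        xmin = .data$from, xmax = .data$to, fill = .data$habitat
      ),
      ymin = -Inf, ymax = Inf, alpha = 0.15, inherit.aes = FALSE
    ) +
      ggplot2::scale_fill_manual(
        values = c(hotspot = "seagreen", occasional = "firebrick")
      )
  }
  p +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$psi_lo, ymax = .data$psi_hi),
      fill = "grey60", alpha = 0.35
    ) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed") +
    ggplot2::labs(
      x = "Temperature (°C)",
      y = "Integrated probability of thriving ψ"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a respirometry trace
#'
#' O2 concentration against time, coloured by phase, one facet per cycle.
#'
#' @param object A `respirometry_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.respirometry_trace <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$time_s, y = .data$o2_mg_per_l, colour = .data$phase)
  ) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::facet_wrap(~cycle, scales = "free_x") +
    ggplot2::labs(x = "Time (s)", y = "O2 (mg/L)") +
    ggplot2::theme_minimal()
}
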