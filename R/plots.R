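#' Cost-effectiveness plane for PSA draws
#'
#' Scatter of the per-iteration incremental effect (reduction in pneumonia
#' proportion, horizontal) against incremental cost (vertical), with the
#' origin axes drawn; mass below the horizontal axis and right of the
#' vertical axis favours the mouthwash intervention.
#'
#' @param object A `psa_output`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psa_output <- function(object, ...) {
  ggplot2::ggplot(object$draws,
                  ggplot2::aes(x = .data$delta_effect, y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.6, colour = "#2c7fb8") +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::geom_point(
      data = object$summary,
      ggplot2::aes(x = .data$mean_delta_effect, y = .data$mean_delta_cost),
      colour = "firebrick", size = 2
    ) +
    ggplot2::labs(
      x = "Reduction in proportion of pneumonia patients",
      y = "Incremental cost (2020 international $)",
      title = "Cost-effectiveness plane"
    ) +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param object A `mw_ceac` tibble from [ceac()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mw_ceac <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$wtp, y = .data$probability_cost_effective)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Willingness to pay per unit reduction in pneumonia proportion ($)",
      y = "Probability mouthwash is cost-effective",
      title = "Cost-effectiveness acceptability curve"
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.psa_output
#' @export
plot_ce_plane <- function(object, ...) autoplot.psa_output(object, ...)

#' @rdname autoplot.mw_ceac
#' @export
plot_ceac <- function(object, ...) autoplot.mw_ceac(object, ...)
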