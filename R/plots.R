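#' Bar chart of disease-category shares for a finding class
#'
#' @param findings Findings tibble.
#' @param class Finding class to plot (default `"ACMG_SF"`).
#' @return A ggplot object.
#' @export
plot_category_breakdown <- function(findings, class = "ACMG_SF") {
  bd <- category_breakdown(findings, class)
  ggplot2::ggplot(
    bd,
    ggplot2::aes(x = stats::reorder(.data$category, -.data$n), y = .data$n)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.1f%%", .data$percent)), vjust = -0.4
    ) +
    ggplot2::labs(
      x = "Disease category", y = "Findings",
      title = sprintf("%s findings by disease category", class)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a screen's per-class participant frequencies
#'
#' @param object An `sf_screen`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sf_screen
#' @export
autoplot.sf_screen <- function(object, ...) {
  cf <- object$summary$class_freq
  ggplot2::ggplot(
    cf,
    ggplot2::aes(x = stats::reorder(.data$label, -.data$percent_raw),
                 y = .data$percent_raw)
  ) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::geom_text(
      ggplot2::aes(label = sprintf("%.2f%%", .data$percent_raw)), vjust = -0.4
    ) +
    ggplot2::labs(
      x = NULL, y = "Participant-level frequency (%)",
      title = "Finding frequencies by reporting class"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
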