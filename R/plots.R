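#' Plot per-image audit results
#'
#' Scatter of detected label area fraction against vertical placement of the
#' label center, with the two FDA rule boundaries drawn; each point is one
#' post with a detected warning.
#'
#' @param results Per-image tibble from [run_audit()] /
#'   [evaluate_compliance_all()] (needs `found`, `area_fraction`, `y0`,
#'   `y1`, and image height via `image_height`).
#' @param image_height Image height in pixels used to normalise placement.
#' @return A ggplot object.
#' @export
plot_compliance <- function(results, image_height) {
  df <- results |>
    filter(.data$found) |>
    mutate(center_rel = ((.data$y0 + .data$y1) / 2) / image_height)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$area_fraction, y = .data$center_rel)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = 0.20, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(
      x = "label area / post area",
      y = "label center (fraction of height, top = 0)",
      title = "Warning-label size and placement vs FDA rules",
      subtitle = "dashed lines: 20% area rule and upper-portion boundary"
    ) +
    ggplot2::theme_minimal()
}

#' Forest plot of incidence rate ratios
#'
#' IRRs and Wald 95% CIs from a fitted engagement model, one row per model
#' term, on a log scale with the null (IRR = 1) marked.
#'
#' @param object An `nb_fit` from [fit_nb_mixed()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nb_fit <- function(object, ...) {
  df <- tidy(object) |> filter(.data$term != "(Intercept)")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$irr, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high), height = 0.2
    ) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "incidence rate ratio (log scale)", y = NULL,
      title = sprintf("Engagement model: %s", object$outcome)
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
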