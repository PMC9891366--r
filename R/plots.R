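#' Violin-style plot of motif contribution distributions
#'
#' Functional groups ordered by mean contribution (most stabilizing on
#' the left); groups below their reporting threshold are drawn
#' translucent.
#'
#' @param motif_contribs Tibble with columns `pattern` and
#'   `epsilon_motif` (kJ per mol of atoms), e.g. the [run_attribute()]
#'   output.
#' @param min_count Reporting threshold (groups with fewer instances are
#'   flagged, default 200).
#' @return A ggplot.
#' @export
plot_motif_distributions <- function(motif_contribs, min_count = 200L) {
  ord <- motif_contribs |>
    dplyr::group_by(.data$pattern) |>
    dplyr::summarise(
      mean = mean(.data$epsilon_motif), count = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$mean)
  tab <- motif_contribs |>
    dplyr::mutate(
      pattern = factor(.data$pattern, levels = ord$pattern),
      low_sample = .data$pattern %in% ord$pattern[ord$count < min_count]
    )
  ggplot2::ggplot(
    tab,
    ggplot2::aes(
      x = .data$pattern, y = .data$epsilon_motif,
      alpha = .data$low_sample
    )
  ) +
    ggplot2::geom_violin(fill = "steelblue", scale = "width", na.rm = TRUE) +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 1.5) +
    ggplot2::scale_alpha_manual(
      values = c(`FALSE` = 1, `TRUE` = 0.35), guide = "none"
    ) +
    ggplot2::labs(
      x = NULL, y = "motif contribution (kJ / mol of atoms)"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Parity plot of predicted versus reference lattice energies
#'
#' @param pred,truth Aligned numeric vectors (kJ per mol of atoms).
#' @param label Plot subtitle (e.g. the feature space).
#' @return A ggplot with the identity line and the RMSE annotated.
#' @export
plot_parity <- function(pred, truth, label = NULL) {
  m <- evaluate_model(pred, truth)
  ggplot2::ggplot(
    tibble::tibble(pred = pred, truth = truth),
    ggplot2::aes(x = .data$truth, y = .data$pred)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = "reference delta_c (kJ / mol of atoms)",
      y = "predicted delta_c (kJ / mol of atoms)",
      subtitle = label,
      caption = sprintf("RMSE %.3g, MAE %.3g kJ/mol-atom", m$rmse, m$mae)
    ) +
    ggplot2::theme_minimal()
}
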