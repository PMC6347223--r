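# ggplot2 views of cohort summaries: class-fraction bars (mean +/- SD over
# replicates), alteration boxes (median and quartiles), and
# increase/decrease splits among damaged cells.

#' Class-fraction bar chart
#'
#' Mean class fractions with replicate SD error bars, one panel per recovery
#' time, coloured by damage class.
#'
#' @param summary A `cryo_summary` from [summarize_cohort()].
#' @return A ggplot object.
#' @export
plot_class_fractions <- function(summary) {
  df <- summary$class_fractions |>
    mutate(recovery = factor(paste0(.data$recovery_min, " min"),
                             paste0(sort(unique(.data$recovery_min)), " min")))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition,
                                   y = .data$mean_fraction,
                                   fill = .data$class)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.85), width = 0.8) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$mean_fraction - .data$sd_fraction, 0),
                   ymax = pmin(.data$mean_fraction + .data$sd_fraction, 1)),
      position = ggplot2::position_dodge(0.85), width = 0.25, linewidth = 0.3
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$recovery)) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "Fraction of cells", fill = "Class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @rdname plot_class_fractions
#' @param object A `cryo_summary`.
#' @param ... Unused.
#' @export
autoplot.cryo_summary <- function(object, ...) {
  plot_class_fractions(object)
}

#' Alteration median/quartile plot
#'
#' Crossbar display of per-stratum alteration medians with the 25th-75th
#' percentile box, faceted by parameter and recovery time.
#'
#' @param summary A `cryo_summary`.
#' @param parameter Optional single parameter
#'   (`"delta_nu"`, `"delta_F"`, `"delta_L"`) to restrict the panels.
#' @return A ggplot object.
#' @export
plot_delta_summaries <- function(summary, parameter = NULL) {
  df <- summary$delta_summaries
  if (!is.null(parameter)) {
    df <- df |> filter(.data$parameter %in% !!parameter)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$median)) +
    ggplot2::geom_crossbar(
      ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
      width = 0.6, fill = "grey85", linewidth = 0.35
    ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::facet_grid(
      rows = ggplot2::vars(.data$parameter),
      cols = ggplot2::vars(.data$recovery_min),
      labeller = ggplot2::labeller(
        recovery_min = function(x) paste0(x, " min")
      )
    ) +
    ggplot2::labs(x = NULL, y = "Alteration (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Increase/decrease split among damaged cells
#'
#' Stacked bars of the fraction of class II/III cells whose parameter
#' increased versus decreased, per stratum.
#'
#' @param summary A `cryo_summary`.
#' @param parameter `"delta_nu"`, `"delta_F"` or `"delta_L"`.
#' @return A ggplot object.
#' @export
plot_direction_split <- function(summary,
                                 parameter = c("delta_nu", "delta_F",
                                               "delta_L")) {
  parameter <- match.arg(parameter)
  df <- summary$direction_splits |>
    filter(.data$parameter == !!parameter) |>
    tidyr::pivot_longer(c("frac_increased", "frac_decreased"),
                        names_to = "direction", values_to = "fraction") |>
    mutate(direction = ifelse(.data$direction == "frac_increased",
                              "increased", "decreased"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$fraction,
                                   fill = .data$direction)) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::facet_wrap(ggplot2::vars(.data$recovery_min),
                        labeller = ggplot2::labeller(
                          .default = function(x) paste0(x, " min"))) +
    ggplot2::labs(x = NULL, y = "Fraction of damaged cells",
                  fill = parameter) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
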