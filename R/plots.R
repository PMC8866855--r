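#' Area-circularity gate scatter
#'
#' Scatter of per-cell area versus circularity with the classification gates
#' drawn (area 250 um2, circularity 0.16 and 0.5), coloured by assigned
#' class — the standard stratification view of a quantified field.
#'
#' @param records per-cell tibble with `area_um2`, `circularity`, `class`.
#' @param area_cutoff_um2,circularity_cutoff,infiltrated_cutoff gate values.
#' @return A ggplot object.
#' @export
plot_gate_scatter <- function(records, area_cutoff_um2 = 250,
                              circularity_cutoff = 0.16,
                              infiltrated_cutoff = 0.5) {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$area_um2, y = .data$circularity,
                               colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.7, size = 1.5) +
    ggplot2::geom_vline(xintercept = area_cutoff_um2, linetype = "dotted") +
    ggplot2::geom_hline(yintercept = circularity_cutoff,
                        linetype = "dotted") +
    ggplot2::geom_hline(yintercept = infiltrated_cutoff,
                        linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = expression("Area (" * mu * m^2 * ")"),
                  y = "Circularity", colour = "Class") +
    ggplot2::theme_minimal()
}

#' Marker intensity by morphological class
#'
#' Violin plot of per-cell marker (Tmem119) mean gray level by class, with
#' the median and quartiles marked.
#'
#' @param records per-cell tibble with `class` and `mean_tmem_total`.
#' @return A ggplot object.
#' @export
plot_marker_by_class <- function(records) {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$class, y = .data$mean_tmem_total,
                               fill = .data$class)) +
    ggplot2::geom_violin(alpha = 0.6, show.legend = FALSE) +
    ggplot2::stat_summary(fun = median, geom = "crossbar", width = 0.4,
                          linewidth = 0.3, show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "Tmem119 mean gray level") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.iba1_run <- function(object, ...) {
  plot_gate_scatter(object$records)
}
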