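#' Volcano plot of a differential-expression result
#'
#' @param object A `de_result` from [de_linear_model()].
#' @param ... Unused.
#' @return A ggplot object: log2 fold change against -log10 q-value,
#'   DE calls highlighted by direction.
#' @export
autoplot.de_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$log2fc, y = -log10(.data$q_value), colour = .data$direction
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(
      values = c(up = "#c0392b", down = "#2471a3", none = "grey60")
    ) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "q_threshold")),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_vline(
      xintercept = c(-1, 1) * log2(attr(object, "fc_threshold")),
      linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 q-value",
                  colour = "call") +
    ggplot2::theme_minimal()
}

#' Module size barplot
#'
#' @param object A `module_assignment` from [detect_modules()].
#' @param ... Unused.
#' @return A ggplot object of module sizes (unassigned genes included as
#'   their own bar).
#' @export
autoplot.module_assignment <- function(object, ...) {
  counts <- dplyr::count(tibble::as_tibble(object), .data$module)
  ggplot2::ggplot(counts, ggplot2::aes(
    x = stats::reorder(.data$module, -.data$n), y = .data$n
  )) +
    ggplot2::geom_col(fill = "#5d6d7e") +
    ggplot2::labs(x = "module", y = "genes") +
    ggplot2::theme_minimal()
}

#' Gestational-age trend scatter of percent-of-control biomarker levels
#'
#' Scatter of percent-of-control measurements against gestational week,
#' one facet or colour per marker, with the 100% control reference line
#' and the first-trimester cutoff marked.
#'
#' @param measurements Tibble `marker`, `week`, `percent_of_control`.
#' @param cutoff_week First-trimester boundary (default 12).
#' @return A ggplot object.
#' @export
plot_ga_trend <- function(measurements, cutoff_week = 12) {
  ggplot2::ggplot(tibble::as_tibble(measurements), ggplot2::aes(
    x = .data$week, y = .data$percent_of_control, colour = .data$marker
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::geom_hline(yintercept = 100, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = cutoff_week, linetype = "dotted") +
    ggplot2::labs(x = "gestational week", y = "% of control") +
    ggplot2::theme_minimal()
}

#' Differential-methylation classification plot
#'
#' Methylation ratio difference against -log10 p per CpG, coloured by the
#' mild/moderate/strong class, with the classification thresholds marked.
#'
#' @param dm Output of [compare_groups()] or [compare_groups_clinical()].
#' @param alpha Significance gate drawn as a horizontal line (default 0.05).
#' @return A ggplot object.
#' @export
plot_dm_classes <- function(dm, alpha = 0.05) {
  ggplot2::ggplot(tibble::as_tibble(dm), ggplot2::aes(
    x = .data$delta, y = -log10(.data$p_value), colour = .data$class
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_manual(values = c(
      none = "grey60", mild = "#f1c40f", moderate = "#e67e22",
      strong = "#c0392b"
    )) +
    ggplot2::geom_vline(xintercept = as.vector(outer(c(-1, 1), c(0.125, 0.25, 0.5))),
                        linetype = "dotted", colour = "grey50") +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "methylation ratio difference", y = "-log10 p") +
    ggplot2::theme_minimal()
}
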