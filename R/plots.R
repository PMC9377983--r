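# ggplot2 graphics for the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a displacement PDF with its half-maximum width
#'
#' @param object A `displacement_pdf`.
#' @param xlim Displacement window to show, um.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.displacement_pdf <- function(object, xlim = c(-60, 60), ...) {
  df <- as_tibble(object)
  fw <- tryCatch(measure_fwhm(object), error = function(e) NA_real_)
  pk <- max(df$density)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$displacement, .data$density)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::coord_cartesian(xlim = xlim) +
    ggplot2::labs(x = "displacement (µm)",
                  y = "probability density (1/µm)",
                  title = if (is.finite(fw))
                    sprintf("Displacement PDF, FWHM = %.1f µm", fw)
                  else "Displacement PDF") +
    ggplot2::theme_minimal()
  if (is.finite(fw)) {
    p <- p + ggplot2::annotate("segment", x = -fw / 2, xend = fw / 2,
                               y = pk / 2, yend = pk / 2,
                               colour = "#d95f02")
  }
  p
}

#' Heatmap of a Spearman correlation matrix
#'
#' @param object A `spearman_matrix`.
#' @param digits Decimals for the printed coefficients.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.spearman_matrix <- function(object, digits = 2, ...) {
  vars <- rownames(object$rho)
  df <- tidyr::expand_grid(var1 = vars, var2 = vars) |>
    dplyr::mutate(rho = as.vector(t(object$rho)))
  ggplot2::ggplot(df, ggplot2::aes(.data$var2, .data$var1, fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.*f", digits, .data$rho)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "rho") +
    ggplot2::theme_minimal()
}

#' Group box plots of a per-subject metric
#'
#' Box-and-whisker comparison of one variable across the study groups,
#' one panel per muscle.
#'
#' @param data Subjects tibble (e.g. from [simulate_cohort()]).
#' @param variable Column to plot.
#' @return A ggplot.
#' @export
plot_group_boxplots <- function(data, variable) {
  ggplot2::ggplot(data, ggplot2::aes(.data$group, .data[[variable]],
                                     fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = 1, show.legend = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$muscle)) +
    ggplot2::labs(x = NULL, y = variable) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
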