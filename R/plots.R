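#' @exportS3Method
autoplot.soft_threshold_scan <- function(object, ...) {
  ggplot2::ggplot(object$scan, ggplot2::aes(x = .data$power, y = .data$signed_r2)) +
    ggplot2::geom_hline(yintercept = object$fit_cut, linetype = "dashed",
                        color = "red") +
    ggplot2::geom_text(ggplot2::aes(label = .data$power), size = 3) +
    ggplot2::labs(x = "Soft-threshold power",
                  y = "Signed scale-free fit R²",
                  title = "Scale-free topology fit") +
    ggplot2::theme_minimal()
}

#' Module size and eigengene variance summary plot
#'
#' @param net A `coexpression_network`.
#' @return A ggplot object.
#' @export
plot_module_summary <- function(net) {
  sizes <- dplyr::count(net$modules, .data$module, name = "size")
  df <- dplyr::left_join(sizes, net$var_explained, by = "module")
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$module, -.data$size),
                                   y = .data$size, fill = .data$module)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.0f%%", 100 * .data$var_explained)), vjust = -0.4, size = 3) +
    ggplot2::scale_fill_identity() +
    ggplot2::labs(x = NULL, y = "Genes",
                  title = "Module sizes (label: eigengene variance explained)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
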