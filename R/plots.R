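#' Per-class mean spectra with standard-error ribbons
#'
#' @param x A [raman_spectra] tibble of labeled measurement spectra.
#' @return A ggplot.
#' @export
plot_class_means <- function(x) {
  d <- tibble::as_tibble(x) |>
    dplyr::filter(.data$frame_kind == "measurement", !is.na(.data$tissue_class)) |>
    dplyr::group_by(.data$tissue_class, .data$wavenumber) |>
    dplyr::summarise(mean = mean(.data$intensity),
                     se = stats::sd(.data$intensity) / sqrt(dplyr::n()),
                     .groups = "drop") |>
    dplyr::mutate(tissue_class = factor(.data$tissue_class, tissue_classes()))
  ggplot2::ggplot(d, ggplot2::aes(.data$wavenumber, .data$mean,
                                  color = .data$tissue_class,
                                  fill = .data$tissue_class)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.25, color = NA) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = expression("Raman shift (cm"^-1 * ")"),
                  y = "Normalized intensity",
                  color = "Tissue", fill = "Tissue") +
    ggplot2::theme_minimal()
}

#' Principal-component score scatter
#'
#' @param scores Score matrix (rows = spectra, >= 2 columns).
#' @param labels Tissue class per row.
#' @return A ggplot of PC1 vs PC2.
#' @export
plot_scores <- function(scores, labels) {
  d <- tibble::tibble(PC1 = scores[, 1], PC2 = scores[, 2],
                      tissue_class = factor(labels, tissue_classes()))
  ggplot2::ggplot(d, ggplot2::aes(.data$PC1, .data$PC2,
                                  color = .data$tissue_class)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(color = "Tissue") +
    ggplot2::theme_minimal()
}

#' @method autoplot feature_mask
#' @export
autoplot.feature_mask <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$wavenumber, .data$statistic)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point(data = dplyr::filter(tibble::as_tibble(object), .data$keep),
                        color = "firebrick", size = 0.6) +
    ggplot2::geom_hline(yintercept = attr(object, "f_critical"),
                        linetype = 2) +
    ggplot2::labs(x = expression("Raman shift (cm"^-1 * ")"),
                  y = "Fisher criterion (F)") +
    ggplot2::theme_minimal()
}

#' @method autoplot band_summary
#' @export
autoplot.band_summary <- function(object, ...) {
  d <- dplyr::mutate(object$bands,
                     tissue_class = factor(.data$tissue_class, tissue_classes()),
                     label = sprintf("%s\n%g-%g", .data$component, .data$lo, .data$hi))
  stars <- dplyr::distinct(d, .data$label, .data$tier)
  ggplot2::ggplot(d, ggplot2::aes(.data$label, .data$mean,
                                  fill = .data$tissue_class)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           position = ggplot2::position_dodge(0.9), width = 0.3) +
    ggplot2::geom_text(data = stars,
                       ggplot2::aes(.data$label, y = Inf,
                                    label = ifelse(.data$tier == "ns", "", .data$tier)),
                       vjust = 1.2, inherit.aes = FALSE) +
    ggplot2::labs(x = NULL, y = "Summed band intensity", fill = "Tissue") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
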