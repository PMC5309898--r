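#' Plot an fd window scan along the genome
#'
#' @param windows Window tibble from [fd_windows()].
#' @return A ggplot object (fd per window, panelled by scaffold).
#' @export
plot_fd_scan <- function(windows) {
  ggplot2::ggplot(dplyr::filter(windows, !is.na(.data$fd)),
                  ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                               y = .data$fd)) +
    ggplot2::geom_line(colour = "grey40", linewidth = 0.3) +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::facet_wrap(~scaffold, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(f[d])) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

ancestry_palette <- c(congolese = "#c23b22", upper_nile = "#2e6fba",
                      unassigned = "grey70", no_data = "grey90")

#' Plot painted ancestry windows along a scaffold
#'
#' @param windows Window tibble from [ancestry_windows()].
#' @return A ggplot object: one coloured tile per window.
#' @export
plot_ancestry_painting <- function(windows) {
  ggplot2::ggplot(windows,
                  ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6,
                               ymin = 0, ymax = 1, fill = .data$colour)) +
    ggplot2::geom_rect() +
    ggplot2::facet_wrap(~scaffold, ncol = 1, strip.position = "left") +
    ggplot2::scale_fill_manual(values = ancestry_palette) +
    ggplot2::labs(x = "position (Mb)", y = NULL, fill = "ancestry") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Histogram of ancestry tract lengths by colour
#'
#' @param tract_summary Tibble from [tract_length_summary()].
#' @return A ggplot object.
#' @export
plot_tract_lengths <- function(tract_summary) {
  ggplot2::ggplot(tract_summary,
                  ggplot2::aes(x = .data$bin / 1000, y = .data$n,
                               fill = .data$colour)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = ancestry_palette) +
    ggplot2::labs(x = "tract length bin (kb)", y = "tract count",
                  fill = "ancestry") +
    ggplot2::theme_minimal()
}

#' @describeIn enrichment Bar plot of per-category outlier proportions with
#'   Fisher P values against the reference, in the style of a category
#'   enrichment figure.
#' @param object An `ht_enrichment` object.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.ht_enrichment <- function(object, ...) {
  tab <- object$table |> dplyr::filter(.data$n_snps > 0)
  lab <- ifelse(is.na(tab$p_vs_reference), "",
                sprintf("p = %.3g", tab$p_vs_reference))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$category,
                                    y = .data$outlier_proportion)) +
    ggplot2::geom_col(fill = "grey55") +
    ggplot2::geom_text(ggplot2::aes(
      label = paste0("n=", .data$n_snps, "\n", lab)),
      vjust = -0.2, size = 3) +
    ggplot2::labs(x = "ancestry category", y = "proportion of FST outliers") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
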