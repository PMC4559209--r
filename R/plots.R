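matrix_plot_data <- function(mat, fragments) {
  n <- nrow(mat)
  tibble::tibble(
    i = rep(seq_len(n), times = n),
    j = rep(seq_len(n), each = n),
    value = as.vector(mat),
    chrom_i = fragments$chrom[rep(seq_len(n), times = n)])
}

chromosome_boundaries <- function(fragments) {
  which(fragments$chrom[-1] != fragments$chrom[-nrow(fragments)]) + 0.5
}

#' Heatmap of a contact map or comparison matrix
#'
#' Sequential palette for contact frequencies, diverging palette centred at
#' zero for comparison kinds; missing entries are drawn in grey and
#' chromosome boundaries as lines.
#'
#' @param x An `interaction_matrix`, `normalized_matrix` or
#'   `comparison_result`.
#' @param log_scale Log10-scale the fill for count-like matrices
#'   (default TRUE, ignored for comparison kinds).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_contact_map <- function(x, log_scale = TRUE, ...) {
  diverging <- inherits(x, "comparison_result")
  if (diverging) {
    mat <- x$matrix
    frags <- x$fragments
    title <- x$kind
  } else {
    inp <- as_dense_input(x)
    mat <- inp$mat
    frags <- inp$fragments
    title <- if (inherits(x, "normalized_matrix")) x$method else "counts"
  }
  df <- matrix_plot_data(mat, frags)
  if (!diverging && log_scale) df$value <- log10(df$value + 1)
  bounds <- chromosome_boundaries(frags)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                        fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse(expand = c(0, 0)) +
    ggplot2::scale_x_continuous(expand = c(0, 0)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, title = title) +
    ggplot2::theme_minimal()
  if (diverging) {
    p <- p + ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                           high = "#B2182B", midpoint = 0,
                                           na.value = "grey80")
  } else {
    p <- p + ggplot2::scale_fill_gradient(low = "white", high = "#B2182B",
                                          na.value = "grey80")
  }
  if (length(bounds) > 0) {
    p <- p + ggplot2::geom_hline(yintercept = bounds, linewidth = 0.2) +
      ggplot2::geom_vline(xintercept = bounds, linewidth = 0.2)
  }
  p
}

#' Render a heatmap to an image file
#'
#' @param x A matrix-like result accepted by [plot_contact_map()].
#' @param path Output image path (PNG by extension).
#' @param width,height Size in inches.
#' @param ... Passed to [plot_contact_map()].
#' @return The path, invisibly.
#' @export
render_heatmap <- function(x, path, width = 6, height = 6, ...) {
  p <- plot_contact_map(x, ...)
  ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
  invisible(path)
}

#' @export
autoplot.comparison_result <- function(object, ...) {
  plot_contact_map(object, ...)
}

#' @export
autoplot.normalized_matrix <- function(object, ...) {
  plot_contact_map(object, ...)
}

#' @export
autoplot.interaction_matrix <- function(object, ...) {
  plot_contact_map(object, ...)
}

#' @export
autoplot.ide_result <- function(object, ...) {
  tab <- object$table
  tab <- tab[tab$mean_frequency > 0, ]
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$distance,
                                    y = .data$mean_frequency)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "#B2182B") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "genomic distance (bp)",
                  y = "mean interaction frequency",
                  title = sprintf("IDE = %.3f", object$slope)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.compartment_result <- function(object, ...) {
  df <- object$fragments
  df$index <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$fpc,
                                   fill = .data$label)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c("A-like" = "#B2182B",
                                          "B-like" = "#2166AC",
                                          "masked" = "grey70")) +
    ggplot2::labs(x = "fragment", y = "FPC score") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sampling_test_result <- function(object, ...) {
  df <- tibble::tibble(statistic = object$null_statistics)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$statistic)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "#B2182B") +
    ggplot2::labs(x = "null statistic", y = "count",
                  title = sprintf("observed vs. %d balanced sets, p = %.3g",
                                  object$n_sets, object$p_value)) +
    ggplot2::theme_minimal()
}
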