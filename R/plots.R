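# ggplot2 graphics for the main result types.

#' Volcano plot of a DEG table
#'
#' @param deg_table Output of [call_degs()].
#' @param label_threshold Not used for labelling (kept minimal); points
#'   are colored by direction.
#' @return A ggplot object.
#' @export
plot_volcano <- function(deg_table, label_threshold = NULL) {
  ggplot2::ggplot(deg_table,
                  ggplot2::aes(x = .data$log2fc,
                               y = -log10(pmax(.data$p_value, 1e-300)),
                               colour = .data$direction)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::scale_colour_manual(
      values = c(up = "firebrick", down = "steelblue", ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p", colour = NULL) +
    ggplot2::theme_minimal()
}

#' PCA score plot
#'
#' @param object A `pca_result`.
#' @param ... Unused.
#' @return A ggplot object (PC1 vs PC2, colored by group when known).
#' @export
autoplot.pca_result <- function(object, ...) {
  sc <- object$scores
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  p <- if ("group" %in% names(sc)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), size = 3)
  } else {
    p + ggplot2::geom_point(size = 3)
  }
  p +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])) +
    ggplot2::theme_minimal()
}

#' Log-log box-counting fit plot
#'
#' @param object A `fractal_estimate`.
#' @param ... Unused.
#' @return A ggplot object of `log N(s)` vs `log(1/s)` with the fit line.
#' @export
autoplot.fractal_estimate <- function(object, ...) {
  df <- tibble::tibble(x = log(1 / object$sizes), y = log(object$counts))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$dimension,
                         intercept = object$intercept,
                         linetype = 2, colour = "firebrick") +
    ggplot2::labs(x = "log(1 / box size)", y = "log N(boxes)",
                  subtitle = sprintf("D = %.3f, R2 = %.4f",
                                     object$dimension, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Cumulative fold-change distribution plot
#'
#' @param ecdf_tbl Output of [cumulative_fc_distribution()].
#' @return A ggplot object, one curve per cluster.
#' @export
plot_cumulative_fc <- function(ecdf_tbl) {
  ggplot2::ggplot(ecdf_tbl,
                  ggplot2::aes(x = .data$log2fc, y = .data$cum_pct,
                               colour = factor(.data$cluster))) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "log2 fold change", y = "cumulative %",
                  colour = "cluster") +
    ggplot2::theme_minimal()
}

#' Enrichment bar plot
#'
#' Horizontal fold-enrichment bars for the top terms, optionally split
#' into up/down fractions when present.
#'
#' @param records Output of [hypergeom_enrich()] (optionally after
#'   [updown_fractions()]).
#' @param top Number of terms to show.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(records, top = 15) {
  df <- head(dplyr::arrange(records, .data$p_value), top)
  df$name <- factor(df$name, levels = rev(df$name))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fold_enrichment,
                                   y = .data$name)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "fold enrichment", y = NULL) +
    ggplot2::theme_minimal()
}
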