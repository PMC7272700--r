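# broom-style tidiers for the package's fitted objects.

#' Tidy a cluster result
#'
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return The per-feature assignment tibble.
#' @export
tidy.cluster_result <- function(x, ...) x$assignments

#' Glance at a cluster result
#'
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return One-row tibble: `k`, `n`, `tot_withinss`, per-cluster sizes.
#' @export
glance.cluster_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(k = x$k, n = sum(x$sizes), tot_withinss = x$tot_withinss),
    tibble::as_tibble(setNames(as.list(x$sizes),
                               sprintf("size_%d", seq_along(x$sizes))))
  )
}

#' Tidy a fractal estimate
#'
#' @param x A `fractal_estimate`.
#' @param ... Unused.
#' @return Tibble of box sizes and occupied-box counts.
#' @export
tidy.fractal_estimate <- function(x, ...) {
  tibble::tibble(box_size = x$sizes, n_boxes = x$counts)
}

#' Glance at a fractal estimate
#'
#' @param x A `fractal_estimate`.
#' @param ... Unused.
#' @return One-row tibble: `dimension`, `r_squared`, `n_sizes`.
#' @export
glance.fractal_estimate <- function(x, ...) {
  tibble::tibble(dimension = x$dimension, r_squared = x$r_squared,
                 n_sizes = length(x$sizes))
}

#' Tidy an integration network
#'
#' @param x An `integration_network`.
#' @param ... Unused.
#' @return The bipartite edge tibble.
#' @export
tidy.integration_network <- function(x, ...) x$edges

#' Glance at an integration network
#'
#' @param x An `integration_network`.
#' @param ... Unused.
#' @return One-row tibble: `n_mirnas`, `n_genes`, `n_edges`,
#'   `n_overlap_edges`.
#' @export
glance.integration_network <- function(x, ...) {
  tibble::tibble(n_mirnas = nrow(x$mirna_nodes),
                 n_genes = nrow(x$gene_nodes),
                 n_edges = nrow(x$edges),
                 n_overlap_edges = nrow(x$overlap))
}

#' Tidy a PCA result
#'
#' @param x A `pca_result`.
#' @param ... Unused.
#' @return The sample-scores tibble.
#' @export
tidy.pca_result <- function(x, ...) x$scores

#' Glance at a PCA result
#'
#' @param x A `pca_result`.
#' @param ... Unused.
#' @return One-row tibble with PC1/PC2 variance fractions.
#' @export
glance.pca_result <- function(x, ...) {
  tibble::tibble(var_pc1 = x$var_explained[1],
                 var_pc2 = if (length(x$var_explained) > 1)
                   x$var_explained[2] else NA_real_)
}
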