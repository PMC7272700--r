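# Expression-stability analysis: row standardization, k-means clustering
# of DEGs, percent CV of per-sample fold changes, cumulative fold-change
# distributions, sample PCA, and detection of the near-control case
# subgroup.

#' Row z-scores
#'
#' Standardizes each row to mean 0 and SD 1. Zero-variance rows become
#' all-zero with a warning.
#'
#' @param mat Numeric matrix, or tibble with a `feature_id` column.
#' @param sd_type `"population"` (divide by n; the usual z-score
#'   convention) or `"sample"` (divide by n - 1).
#' @return Same shape as the input.
#' @export
zscore_rows <- function(mat, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  tbl <- is.data.frame(mat)
  m <- if (tbl) feature_matrix(mat) else mat
  mu <- rowMeans(m)
  cen <- m - mu
  n <- ncol(m)
  denom <- if (sd_type == "population") n else n - 1
  s <- sqrt(rowSums(cen^2) / denom)
  flat <- s == 0
  if (any(flat)) {
    warning(sum(flat), " zero-variance row(s) mapped to zeros")
    s[flat] <- 1
  }
  z <- cen / s
  if (tbl) matrix_to_tibble(z) else z
}

#' K-means clustering of standardized expression
#'
#' Best of `n_init` random restarts (lowest total within-cluster sum of
#' squares), deterministic given `seed`. Cluster labels are renumbered by
#' descending mean of `order_by` (typically the genes' log2 fold changes)
#' so that label 1 holds the most up-regulated cluster; without `order_by`
#' labels are ordered by decreasing cluster size.
#'
#' @param mat Numeric matrix or tibble (rows = features) of z-scores.
#' @param k Number of clusters.
#' @param n_init Random restarts (the study used 10000; smaller values
#'   are fine for well-separated data).
#' @param seed RNG seed.
#' @param order_by Optional numeric vector (one per row) used to order
#'   cluster labels.
#' @return A `cluster_result`: `assignments` tibble (`feature_id`,
#'   `cluster`), `sizes`, `tot_withinss`, `centers`.
#' @export
kmeans_cluster <- function(mat, k = 4, n_init = 100, seed = 1,
                           order_by = NULL) {
  m <- if (is.data.frame(mat)) feature_matrix(mat) else mat
  if (k > nrow(m)) stop("k exceeds the number of rows")
  fit <- with_seed(child_seed(seed, "kmeans"),
                   kmeans(m, centers = k, nstart = n_init, iter.max = 100))
  lab <- fit$cluster
  key <- if (!is.null(order_by)) {
    stopifnot(length(order_by) == nrow(m))
    -vapply(seq_len(k), function(cl) mean(order_by[lab == cl]), numeric(1))
  } else {
    -tabulate(lab, k)
  }
  remap <- integer(k)
  remap[order(key)] <- seq_len(k)
  lab <- remap[lab]
  centers <- fit$centers[order(key), , drop = FALSE]
  rownames(centers) <- seq_len(k)
  structure(list(
    assignments = tibble::tibble(
      feature_id = rownames(m) %||% as.character(seq_len(nrow(m))),
      cluster = lab
    ),
    sizes = tabulate(lab, k),
    tot_withinss = fit$tot.withinss,
    centers = centers,
    k = k
  ), class = "cluster_result")
}

#' Percent CV of per-sample fold changes
#'
#' The study's expression-stability measure:
#' `%CV = 100 * SD(FC over case samples) / mean(FC over case samples)`
#' per gene, summarized as mean +/- SD over a gene set. Uniformly
#' regulated genes have low %CV, variably regulated genes high %CV.
#'
#' @param fc Per-sample fold-change tibble ([per_sample_fold_change()]).
#' @param samples Sample sheet; the case samples are used.
#' @param genes Optional subset of feature ids.
#' @param sd_type `"sample"` (default, n - 1) or `"population"`.
#' @return List with `per_gene` (tibble `feature_id`, `cv_pct`) and
#'   `summary` (tibble `mean_cv`, `sd_cv`, `n`).
#' @export
fold_change_cv <- function(fc, samples, genes = NULL,
                           sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  m <- count_matrix(fc)
  check_samples(samples, colnames(m))
  case <- group_ids(samples, "case")
  if (!is.null(genes)) m <- m[rownames(m) %in% genes, , drop = FALSE]
  x <- m[, case, drop = FALSE]
  mu <- rowMeans(x)
  n <- ncol(x)
  denom <- if (sd_type == "sample") n - 1 else n
  s <- sqrt(rowSums((x - mu)^2) / denom)
  cv <- 100 * s / mu
  per_gene <- tibble::tibble(feature_id = rownames(m), cv_pct = unname(cv))
  list(
    per_gene = per_gene,
    summary = tibble::tibble(mean_cv = mean(cv), sd_cv = sd(cv),
                             n = length(cv))
  )
}

#' Cumulative fold-change distribution per cluster
#'
#' Empirical CDF of log2 fold changes within each cluster, as plotted in
#' cumulative-frequency panels: sorted values against cumulative percent,
#' ending at 100%.
#'
#' @param log2fc Numeric vector of log2 fold changes.
#' @param cluster Parallel vector of cluster labels.
#' @return Tibble: `cluster`, `log2fc`, `cum_pct`.
#' @export
cumulative_fc_distribution <- function(log2fc, cluster) {
  stopifnot(length(log2fc) == length(cluster))
  tibble::tibble(cluster = cluster, log2fc = log2fc) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::arrange(.data$log2fc, .by_group = TRUE) |>
    dplyr::mutate(cum_pct = 100 * dplyr::row_number() / dplyr::n()) |>
    dplyr::ungroup()
}

#' PCA of samples
#'
#' Centered principal-component analysis of samples on log2-scale
#' normalized expression (`log2(x + pseudo_count)`).
#'
#' @param normalized Normalized counts tibble.
#' @param samples Optional sample sheet; group labels are attached to the
#'   scores when given.
#' @param log_transform Take log2 first (default `TRUE`).
#' @param pseudo_count Pseudo-count before the log.
#' @return A `pca_result`: `scores` tibble (`sample_id`, `PC1`, `PC2`,
#'   ..., `group`), `var_explained` fractions.
#' @export
sample_pca <- function(normalized, samples = NULL, log_transform = TRUE,
                       pseudo_count = 1) {
  m <- count_matrix(normalized)
  x <- t(if (log_transform) log2(m + pseudo_count) else m)
  fit <- prcomp(x, center = TRUE, scale. = FALSE)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- tibble::as_tibble(fit$x, rownames = "sample_id")
  if (!is.null(samples)) {
    scores <- dplyr::left_join(scores, samples, by = "sample_id")
  }
  structure(list(scores = scores, var_explained = ve),
            class = "pca_result")
}

#' Near-control case subgroup
#'
#' Average-linkage hierarchical clustering of the case samples on
#' Euclidean distance over DEG z-scores, cut into two branches; the branch
#' whose centroid is nearest the control centroid is the near-control
#' subgroup (the study's "cluster A"). If all case samples are identical
#' the whole case group is returned.
#'
#' @param zmat Z-scored DEG expression (tibble or matrix, columns =
#'   samples).
#' @param samples Sample sheet.
#' @return List: `subgroup` (case sample ids), `distance_to_control` for
#'   both branches, and the `hclust` tree.
#' @export
nearest_subgroup <- function(zmat, samples) {
  m <- if (is.data.frame(zmat)) feature_matrix(zmat) else zmat
  check_samples(samples, colnames(m))
  case <- group_ids(samples, "case")
  ctrl <- group_ids(samples, "control")
  if (length(case) < 2) stop("need at least 2 case samples")
  d <- dist(t(m[, case, drop = FALSE]))
  if (max(d) == 0) {
    return(list(subgroup = case, distance_to_control = NULL, tree = NULL))
  }
  tree <- hclust(d, method = "average")
  branch <- cutree(tree, k = 2)
  ctrl_centroid <- rowMeans(m[, ctrl, drop = FALSE])
  dists <- vapply(1:2, function(b) {
    cen <- rowMeans(m[, case[branch == b], drop = FALSE])
    sqrt(sum((cen - ctrl_centroid)^2))
  }, numeric(1))
  list(subgroup = case[branch == which.min(dists)],
       distance_to_control = dists, tree = tree)
}

#' Re-call DEGs using only the near-control case subgroup
#'
#' Runs the NB Wald test and DEG call on controls plus the subgroup's case
#' samples and intersects the calls with a full-group DEG list, yielding
#' the uniformly regulated reduced DEG set.
#'
#' @param counts Raw counts tibble.
#' @param samples Sample sheet.
#' @param subgroup Case sample ids ([nearest_subgroup()]).
#' @param full_degs Character vector of feature ids called DE on the full
#'   design.
#' @param ... Passed to [call_degs()].
#' @return List: `deg_table` (subgroup-design calls) and `reduced_set`
#'   (intersection with `full_degs`).
#' @export
subgroup_degs <- function(counts, samples, subgroup, full_degs, ...) {
  keep <- samples$group == "control" | samples$sample_id %in% subgroup
  sub_samples <- samples[keep, , drop = FALSE]
  sub_counts <- counts[, c("feature_id", sub_samples$sample_id)]
  tab <- call_degs(nb_wald_test(sub_counts, sub_samples), ...)
  called <- tab$feature_id[tab$direction != "ns"]
  list(deg_table = tab, reduced_set = intersect(called, full_degs))
}
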