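# Gene-set over-representation: GMT parsing, upper-tail hypergeometric
# test with BH correction, fold enrichment, and per-term up/down
# fractions.

#' Read a GMT gene-set collection
#'
#' @param path GMT file (term, description, tab-separated genes).
#' @return Tibble: `term_id`, `name`, `genes` (list column).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t")
  tibble::tibble(
    term_id = vapply(parts, `[[`, character(1), 1),
    name = vapply(parts, function(p) if (length(p) > 1) p[2] else p[1],
                  character(1)),
    genes = lapply(parts, function(p) unique(p[-(1:2)]))
  )
}

#' Hypergeometric gene-set over-representation
#'
#' For each term, with universe size `N`, term size `K` (after
#' intersection with the universe), DE-list size `n` and overlap `k`, the
#' p-value is the upper tail `P(X >= k)` of the hypergeometric
#' distribution; q-values are BH across all tested terms. Terms smaller
#' than `min_term_size` are skipped as noise; records are reported for
#' terms with `k >= 1`.
#'
#' @param de_genes Character vector of DE gene ids; genes outside the
#'   universe are dropped with a message.
#' @param gene_sets Collection tibble ([read_gmt()]).
#' @param universe Background gene universe (e.g. all detected genes).
#' @param min_term_size Minimum term size after harmonization.
#' @return Tibble: `term_id`, `name`, `k`, `K`, `n`, `N`, `p_value`,
#'   `q_value`, `fold_enrichment` = `(k/n)/(K/N)`, `pct_genes_term` =
#'   `100 k / K`, `genes_hit` list column.
#' @export
hypergeom_enrich <- function(de_genes, gene_sets, universe,
                             min_term_size = 3) {
  universe <- unique(universe)
  dropped <- setdiff(de_genes, universe)
  if (length(dropped) > 0) {
    message(length(dropped), " DE gene(s) outside the universe dropped")
  }
  de <- intersect(unique(de_genes), universe)
  if (length(de) == 0) {
    warning("empty DE list after harmonization")
    return(tibble::tibble())
  }
  N <- length(universe); n <- length(de)
  tested <- gene_sets |>
    dplyr::mutate(genes = lapply(.data$genes, intersect, y = universe),
                  K = lengths(.data$genes)) |>
    dplyr::filter(.data$K >= min_term_size)
  res <- tested |>
    dplyr::mutate(
      genes_hit = lapply(.data$genes, intersect, y = de),
      k = lengths(.data$genes_hit),
      n = n, N = N,
      p_value = phyper(.data$k - 1, .data$K, N - .data$K, n,
                       lower.tail = FALSE),
      q_value = benjamini_hochberg(.data$p_value),
      fold_enrichment = (.data$k / n) / (.data$K / N),
      pct_genes_term = 100 * .data$k / .data$K
    ) |>
    dplyr::filter(.data$k >= 1) |>
    dplyr::select("term_id", "name", "k", "K", "n", "N", "p_value",
                  "q_value", "fold_enrichment", "pct_genes_term",
                  "genes_hit") |>
    dplyr::arrange(.data$p_value)
  res
}

#' Per-term up/down-regulated fractions
#'
#' Fractions of each term's DE hits that are up- vs down-regulated, as in
#' direction-colored enrichment bar plots.
#'
#' @param records Output of [hypergeom_enrich()].
#' @param up_set,down_set Disjoint character vectors of up- and
#'   down-regulated gene ids.
#' @return `records` with `frac_up` and `frac_down` columns (summing to 1
#'   whenever `k > 0`).
#' @export
updown_fractions <- function(records, up_set, down_set) {
  if (length(intersect(up_set, down_set)) > 0) {
    stop("up and down sets must be disjoint")
  }
  records |>
    dplyr::mutate(
      frac_up = vapply(.data$genes_hit, function(g) {
        if (length(g) == 0) return(NA_real_)
        mean(g %in% up_set)
      }, numeric(1)),
      frac_down = vapply(.data$genes_hit, function(g) {
        if (length(g) == 0) return(NA_real_)
        mean(g %in% down_set)
      }, numeric(1))
    )
}
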