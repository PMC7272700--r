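# miRNA-target integration: union of per-source predictions, the
# anti-correlation (opposite DE direction) filter, the bipartite network
# with Jaccard-weighted miRNA overlap edges, subnetwork extraction with a
# protein-interaction overlay, and graph exports.

#' Union of per-source miRNA-target predictions
#'
#' A (miRNA, gene) pair is a candidate if reported by at least one
#' prediction source or a validated-target source (union-set rule). Ids
#' are matched case-insensitively against the supplied expression
#' namespaces; unmatched rows are dropped and counted.
#'
#' @param targets Tidy target table: `mirna_id`, `gene_id`, `source`, and
#'   optionally `validated` (otherwise sources named `"validated"` are
#'   flagged).
#' @param mirnas Optional miRNA ids to restrict to (e.g. the DE miRNAs).
#' @param gene_universe,mirna_universe Optional id namespaces for
#'   case-insensitive harmonization.
#' @return Tibble: `mirna_id`, `gene_id`, `sources` (list), `n_sources`,
#'   `validated`; dropped-row count in the `"n_dropped"` attribute.
#' @export
union_targets <- function(targets, mirnas = NULL, gene_universe = NULL,
                          mirna_universe = NULL) {
  stopifnot(all(c("mirna_id", "gene_id", "source") %in% names(targets)))
  if (!"validated" %in% names(targets)) {
    targets$validated <- targets$source == "validated"
  }
  n0 <- nrow(targets)
  if (!is.null(gene_universe)) {
    map <- setNames(gene_universe, tolower(gene_universe))
    targets <- targets |>
      dplyr::mutate(gene_id = unname(map[tolower(.data$gene_id)])) |>
      dplyr::filter(!is.na(.data$gene_id))
  }
  if (!is.null(mirna_universe)) {
    map <- setNames(mirna_universe, tolower(mirna_universe))
    targets <- targets |>
      dplyr::mutate(mirna_id = unname(map[tolower(.data$mirna_id)])) |>
      dplyr::filter(!is.na(.data$mirna_id))
  }
  if (!is.null(mirnas)) {
    targets <- dplyr::filter(targets, .data$mirna_id %in% mirnas)
  }
  out <- targets |>
    dplyr::distinct(.data$mirna_id, .data$gene_id, .data$source,
                    .data$validated) |>
    dplyr::group_by(.data$mirna_id, .data$gene_id) |>
    dplyr::summarise(sources = list(sort(unique(.data$source))),
                     n_sources = length(unique(.data$source)),
                     validated = any(.data$validated), .groups = "drop")
  attr(out, "n_dropped") <- n0 - nrow(targets)
  out
}

#' Anti-correlation filter on candidate pairs
#'
#' Keeps a (miRNA, gene) pair only when both partners are differentially
#' expressed and in opposite directions - the operational reading of
#' "miRNA and target expression should be inversely correlated".
#'
#' @param candidates Candidate pairs ([union_targets()]).
#' @param de_mrna,de_mirna DEG tables ([call_degs()]) with `feature_id`
#'   and `direction`.
#' @return Filtered pairs with `mirna_direction` and `gene_direction`
#'   columns.
#' @export
anticorrelation_filter <- function(candidates, de_mrna, de_mirna) {
  dir_g <- setNames(de_mrna$direction, de_mrna$feature_id)
  dir_m <- setNames(de_mirna$direction, de_mirna$feature_id)
  candidates |>
    dplyr::mutate(
      gene_direction = unname(dir_g[.data$gene_id]),
      mirna_direction = unname(dir_m[.data$mirna_id])
    ) |>
    dplyr::filter(
      !is.na(.data$gene_direction), !is.na(.data$mirna_direction),
      .data$gene_direction %in% c("up", "down"),
      .data$mirna_direction %in% c("up", "down"),
      .data$gene_direction != .data$mirna_direction
    )
}

#' Build the miRNA-target integration network
#'
#' Bipartite miRNA-gene edges (evidence: validated when any supporting
#' source is validated, otherwise predicted), miRNA node degrees, and
#' miRNA-miRNA overlap edges weighted by the Jaccard coefficient
#' `|A n B| / |A u B|` of the two target sets (zero-overlap pairs are
#' suppressed).
#'
#' @param pairs Filtered pairs ([anticorrelation_filter()]).
#' @return An `integration_network`: `edges`, `mirna_nodes`, `gene_nodes`,
#'   `overlap` tibbles.
#' @export
build_network <- function(pairs) {
  edges <- pairs |>
    dplyr::mutate(evidence = ifelse(isTRUE_vec(pairs$validated),
                                    "validated", "predicted"))
  mirna_nodes <- edges |>
    dplyr::group_by(mirna_id = .data$mirna_id) |>
    dplyr::summarise(
      degree = dplyr::n(),
      direction = .data$mirna_direction[1],
      targets = list(sort(unique(.data$gene_id))), .groups = "drop")
  gene_nodes <- edges |>
    dplyr::group_by(gene_id = .data$gene_id) |>
    dplyr::summarise(n_mirnas = dplyr::n(),
                     direction = .data$gene_direction[1], .groups = "drop")
  sets <- setNames(mirna_nodes$targets, mirna_nodes$mirna_id)
  ids <- names(sets)
  overlap <- tibble::tibble(mirna_a = character(), mirna_b = character(),
                            jaccard = numeric())
  if (length(ids) >= 2) {
    cmb <- utils::combn(ids, 2)
    jac <- apply(cmb, 2, function(p) {
      jaccard_index(sets[[p[1]]], sets[[p[2]]])
    })
    overlap <- tibble::tibble(mirna_a = cmb[1, ], mirna_b = cmb[2, ],
                              jaccard = jac) |>
      dplyr::filter(.data$jaccard > 0)
  }
  structure(list(edges = edges, mirna_nodes = mirna_nodes,
                 gene_nodes = gene_nodes, overlap = overlap),
            class = "integration_network")
}

isTRUE_vec <- function(x) if (is.null(x)) FALSE else !is.na(x) & x

#' Jaccard coefficient of two sets
#'
#' @param a,b Vectors treated as sets.
#' @return `|a n b| / |a u b|` (0 when both are empty).
#' @export
jaccard_index <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Induced subnetwork with optional protein-interaction overlay
#'
#' Restricts the network to `gene_set` and the miRNAs regulating those
#' genes. User-supplied interaction edges are overlaid among the genes;
#' interactors absent from the expression analysis are admitted as
#' neutral (direction `"ns"`) nodes.
#'
#' @param network An `integration_network`.
#' @param gene_set Gene ids to keep.
#' @param ppi_edges Optional tibble (`gene_a`, `gene_b`) of interactions.
#' @return An `integration_network` with an extra `ppi_edges` element.
#' @export
subnetwork <- function(network, gene_set, ppi_edges = NULL) {
  edges <- dplyr::filter(network$edges, .data$gene_id %in% gene_set)
  sub <- build_network(edges)
  if (!is.null(ppi_edges)) {
    keep <- ppi_edges$gene_a %in% gene_set | ppi_edges$gene_b %in% gene_set
    ppi <- ppi_edges[keep, , drop = FALSE]
    extra <- setdiff(unique(c(ppi$gene_a, ppi$gene_b)),
                     sub$gene_nodes$gene_id)
    if (length(extra) > 0) {
      sub$gene_nodes <- dplyr::bind_rows(
        sub$gene_nodes,
        tibble::tibble(gene_id = extra, n_mirnas = 0L, direction = "ns")
      )
    }
    sub$ppi_edges <- ppi
  }
  sub
}

#' Genes ranked by number of regulating miRNAs
#'
#' @param network An `integration_network`.
#' @return Tibble sorted descending: `gene_id`, `n_mirnas`, `mirnas`
#'   (list column).
#' @export
coregulation_table <- function(network) {
  network$edges |>
    dplyr::group_by(gene_id = .data$gene_id) |>
    dplyr::summarise(n_mirnas = dplyr::n(),
                     mirnas = list(sort(unique(.data$mirna_id))),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_mirnas), .data$gene_id)
}

#' Convert an integration network to igraph
#'
#' Bipartite miRNA-gene edges typed by evidence, miRNA-miRNA overlap
#' edges carrying Jaccard weights, and any protein-interaction overlay.
#'
#' @param network An `integration_network`.
#' @return An `igraph` graph.
#' @export
as_igraph_network <- function(network) {
  e1 <- tibble::tibble(from = network$edges$mirna_id,
                       to = network$edges$gene_id,
                       type = network$edges$evidence, weight = 1)
  e2 <- tibble::tibble(from = network$overlap$mirna_a,
                       to = network$overlap$mirna_b,
                       type = "overlap", weight = network$overlap$jaccard)
  e3 <- if (!is.null(network$ppi_edges)) {
    tibble::tibble(from = network$ppi_edges$gene_a,
                   to = network$ppi_edges$gene_b, type = "ppi", weight = 1)
  } else NULL
  edges <- dplyr::bind_rows(e1, e2, e3)
  verts <- dplyr::bind_rows(
    tibble::tibble(name = network$mirna_nodes$mirna_id, kind = "mirna",
                   direction = network$mirna_nodes$direction,
                   degree_targets = network$mirna_nodes$degree),
    tibble::tibble(name = network$gene_nodes$gene_id, kind = "gene",
                   direction = network$gene_nodes$direction,
                   degree_targets = NA_integer_)
  )
  verts <- dplyr::bind_rows(
    verts,
    tibble::tibble(name = setdiff(unique(c(edges$from, edges$to)),
                                  verts$name),
                   kind = "gene", direction = "ns",
                   degree_targets = NA_integer_)
  )
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}

#' Write a network as GraphML
#'
#' @param network An `integration_network`.
#' @param path Output file.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(as_igraph_network(network), path, format = "graphml")
  invisible(path)
}

#' Write a network as SIF
#'
#' One line per edge: `source<TAB>interaction<TAB>target`.
#'
#' @param network An `integration_network`.
#' @param path Output file.
#' @export
write_network_sif <- function(network, path) {
  lines <- c(
    sprintf("%s\t%s\t%s", network$edges$mirna_id, network$edges$evidence,
            network$edges$gene_id),
    sprintf("%s\toverlap\t%s", network$overlap$mirna_a,
            network$overlap$mirna_b)
  )
  if (!is.null(network$ppi_edges)) {
    lines <- c(lines, sprintf("%s\tppi\t%s", network$ppi_edges$gene_a,
                              network$ppi_edges$gene_b))
  }
  writeLines(lines, path)
  invisible(path)
}
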