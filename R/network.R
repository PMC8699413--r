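#' Build the enriched-term network
#'
#' Nodes are gene-set terms enriched in at least one cell; each node carries
#' its contributing cells, the union of their overlap genes, and the
#' fraction of contributing cells per blood-draw time point. An undirected
#' edge joins two terms exactly when they share strictly more than
#' `edge_threshold` genes (default 10, i.e. at least 11 shared genes).
#'
#' @param results Per-cell enrichment tibble from [enrich_cells()].
#' @param metadata Cohort metadata (`cell_id`, `time_point`).
#' @param edge_threshold Strict lower bound on shared genes (default 10).
#' @return An object of class `term_network`: a list with `nodes` (tibble
#'   `term_id`, `term_name`, `n_cells`, `n_genes`, `contributing_cells`,
#'   `gene_set`, `frac_A`, `frac_B`, `frac_C`) and `edges` (tibble `from`,
#'   `to`, `shared_gene_count`).
#' @export
build_term_network <- function(results, metadata, edge_threshold = 10) {
  empty_nodes <- tibble(term_id = character(), term_name = character(),
                        n_cells = integer(), n_genes = integer(),
                        contributing_cells = list(), gene_set = list(),
                        frac_A = numeric(), frac_B = numeric(),
                        frac_C = numeric())
  empty_edges <- tibble(from = character(), to = character(),
                        shared_gene_count = integer())
  if (nrow(results) == 0) {
    return(structure(list(nodes = empty_nodes, edges = empty_edges,
                          edge_threshold = edge_threshold),
                     class = "term_network"))
  }
  tp_of <- stats::setNames(metadata$time_point, metadata$cell_id)
  nodes <- results |>
    group_by(.data$term_id, .data$term_name) |>
    summarise(
      contributing_cells = list(unique(.data$cell_id)),
      gene_set = list(unique(unlist(.data$overlap_genes))),
      .groups = "drop"
    ) |>
    mutate(
      n_cells = purrr::map_int(.data$contributing_cells, length),
      n_genes = purrr::map_int(.data$gene_set, length)
    )
  fracs <- purrr::map(nodes$contributing_cells, function(cells) {
    tp <- tp_of[cells]
    tp <- tp[!is.na(tp)]
    if (length(tp) == 0) return(c(A = NA_real_, B = NA_real_, C = NA_real_))
    tab <- table(factor(tp, levels = c("A", "B", "C")))
    as.numeric(tab / sum(tab))
  })
  nodes$frac_A <- purrr::map_dbl(fracs, 1)
  nodes$frac_B <- purrr::map_dbl(fracs, 2)
  nodes$frac_C <- purrr::map_dbl(fracs, 3)
  nodes <- nodes[, names(empty_nodes)]

  edges <- empty_edges
  if (nrow(nodes) > 1) {
    pairs <- utils::combn(seq_len(nrow(nodes)), 2)
    shared <- purrr::map_int(seq_len(ncol(pairs)), function(j) {
      length(intersect(nodes$gene_set[[pairs[1, j]]],
                       nodes$gene_set[[pairs[2, j]]]))
    })
    keep <- shared > edge_threshold
    if (any(keep)) {
      edges <- tibble(
        from = nodes$term_id[pairs[1, keep]],
        to = nodes$term_id[pairs[2, keep]],
        shared_gene_count = shared[keep]
      )
    }
  }
  structure(list(nodes = nodes, edges = edges,
                 edge_threshold = edge_threshold),
            class = "term_network")
}

#' @export
print.term_network <- function(x, ...) {
  cat("<term_network> ", nrow(x$nodes), " terms, ", nrow(x$edges),
      " edges (> ", x$edge_threshold, " shared genes)\n", sep = "")
  invisible(x)
}

#' @rdname build_term_network
#' @param x A `term_network`.
#' @param what `"edges"` (default) or `"nodes"`.
#' @param ... Unused.
#' @method tidy term_network
#' @export
tidy.term_network <- function(x, what = c("edges", "nodes"), ...) {
  what <- match.arg(what)
  if (what == "edges") return(x$edges)
  select(x$nodes, -"contributing_cells", -"gene_set")
}

#' @rdname build_term_network
#' @method glance term_network
#' @export
glance.term_network <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         edge_threshold = x$edge_threshold)
}

as_igraph <- function(network) {
  nodes <- network$nodes |>
    transmute(name = .data$term_id, term_name = .data$term_name,
              n_cells = .data$n_cells, n_genes = .data$n_genes,
              frac_A = .data$frac_A, frac_B = .data$frac_B,
              frac_C = .data$frac_C)
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = nodes)
}

#' Export a term network
#'
#' Writes GraphML (node attributes `term_name`, `n_cells`, `n_genes`,
#' time-point fractions; edge attribute `shared_gene_count`) plus
#' node and edge TSVs that round-trip through [read_network_tables()].
#'
#' @param network A `term_network`.
#' @param graphml,nodes_tsv,edges_tsv Output paths (any may be `NULL` to
#'   skip).
#' @return Invisibly, the paths written.
#' @export
export_network <- function(network, graphml = NULL, nodes_tsv = NULL,
                           edges_tsv = NULL) {
  written <- character(0)
  if (!is.null(graphml)) {
    igraph::write_graph(as_igraph(network), graphml, format = "graphml")
    written <- c(written, graphml)
  }
  if (!is.null(nodes_tsv)) {
    readr::write_tsv(tidy(network, what = "nodes"), nodes_tsv)
    written <- c(written, nodes_tsv)
  }
  if (!is.null(edges_tsv)) {
    readr::write_tsv(network$edges, edges_tsv)
    written <- c(written, edges_tsv)
  }
  invisible(written)
}

#' @rdname export_network
#' @export
read_network_tables <- function(nodes_tsv, edges_tsv) {
  list(
    nodes = readr::read_tsv(nodes_tsv, show_col_types = FALSE),
    edges = readr::read_tsv(edges_tsv, show_col_types = FALSE)
  )
}

#' Plot a term network
#'
#' Fruchterman-Reingold layout with node size mapped to the number of
#' contributing cells (the published convention for this view) or to the
#' number of genes.
#'
#' @param object A `term_network`.
#' @param size_by `"n_cells"` (default) or `"n_genes"`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot term_network
#' @export
autoplot.term_network <- function(object, size_by = c("n_cells", "n_genes"),
                                  seed = 1L, ...) {
  size_by <- match.arg(size_by)
  if (nrow(object$nodes) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void())
  }
  g <- as_igraph(object)
  xy <- withr::with_seed(seed, igraph::layout_with_fr(g))
  nodes <- mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  edges <- object$edges |>
    mutate(
      x = nodes$x[match(.data$from, nodes$term_id)],
      y = nodes$y[match(.data$from, nodes$term_id)],
      xend = nodes$x[match(.data$to, nodes$term_id)],
      yend = nodes$y[match(.data$to, nodes$term_id)]
    )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend),
      colour = "grey70"
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, size = .data[[size_by]],
                   colour = .data$frac_B)
    ) +
    ggplot2::scale_colour_gradient(low = "gold", high = "firebrick",
                                   name = "fraction post-neoadjuvant") +
    ggplot2::labs(size = size_by) +
    ggplot2::theme_void()
}
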