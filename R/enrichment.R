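#' Genes inside a cell's significant CNAs
#'
#' @param calls One cell's calls tibble (`chrom`, `start`, `end`).
#' @param annotation Gene annotation tibble (`gene`, `chrom`, `start`,
#'   `end`).
#' @param mode `"any_overlap"` (gene counted if it overlaps a call by at
#'   least 1 bp; default, robust to bin-resolution breakpoints) or
#'   `"contained"` (gene interval fully inside a call).
#' @return Character vector of unique gene identifiers.
#' @export
genes_in_calls <- function(calls, annotation,
                           mode = c("any_overlap", "contained")) {
  mode <- match.arg(mode)
  if (nrow(calls) == 0) return(character(0))
  hit <- purrr::pmap(calls[, c("chrom", "start", "end")],
                     function(chrom, start, end) {
    same <- annotation$chrom == chrom
    if (mode == "any_overlap") {
      annotation$gene[same & annotation$start < end & annotation$end > start]
    } else {
      annotation$gene[same & annotation$start >= start &
                        annotation$end <= end]
    }
  })
  unique(unlist(hit))
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided (upper-tail) hypergeometric test per gene set: the probability
#' of observing at least the seen overlap between the query and the term,
#' drawing `|query|` genes from a universe of `|universe|` of which `|term|`
#' belong to the set.
#'
#' @param query Character vector of query genes. Genes outside the universe
#'   are dropped with a warning.
#' @param collection Gene-set tibble from [read_gmt()] (columns `term_id`,
#'   `term_name`, `genes`).
#' @param universe Character vector of background genes (typically all
#'   annotated genes).
#' @return Tibble `term_id`, `term_name`, `term_size`, `overlap`, `p`,
#'   `overlap_genes` (list-column). Empty (with a warning) for an empty
#'   query.
#' @export
hypergeometric_enrich <- function(query, collection, universe) {
  empty <- tibble(term_id = character(), term_name = character(),
                  term_size = integer(), overlap = integer(), p = numeric(),
                  overlap_genes = list())
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warn(paste0("dropping ", length(outside), " query gene(s) not in universe"))
    query <- intersect(query, universe)
  }
  if (length(query) == 0) {
    warn("empty query; no enrichment computed")
    return(empty)
  }
  N <- length(unique(universe))
  n <- length(query)
  purrr::pmap(collection, function(term_id, term_name, genes, ...) {
    term <- intersect(unique(genes), universe)
    K <- length(term)
    if (K == 0) return(NULL)
    ov <- intersect(query, term)
    k <- length(ov)
    # P[X >= k], X ~ Hypergeom(N, K, n)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(term_id = term_id, term_name = term_name, term_size = K,
           overlap = k, p = min(p, 1), overlap_genes = list(ov))
  }) |>
    purrr::list_rbind() %||% empty
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, capped at 1; invariant to input
#' order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop_ctcna("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Per-cell enrichment of genes inside significant CNAs
#'
#' Chains [genes_in_calls()], [hypergeometric_enrich()] and [bh_adjust()],
#' retaining terms with adjusted p-value at or below `alpha`.
#'
#' @param calls One cell's calls tibble.
#' @param annotation Gene annotation tibble.
#' @param collection Gene-set tibble from [read_gmt()].
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param mode Gene-overlap mode, see [genes_in_calls()].
#' @param universe Background genes; defaults to all annotated genes (only
#'   annotated genes can enter a query).
#' @return Tibble `term_id`, `term_name`, `term_size`, `overlap`, `p`,
#'   `p_adj`, `overlap_genes`.
#' @export
enrich_cell <- function(calls, annotation, collection, alpha = 0.05,
                        mode = "any_overlap", universe = NULL) {
  universe <- universe %||% unique(annotation$gene)
  query <- genes_in_calls(calls, annotation, mode = mode)
  if (length(query) == 0) {
    return(tibble(term_id = character(), term_name = character(),
                  term_size = integer(), overlap = integer(), p = numeric(),
                  p_adj = numeric(), overlap_genes = list()))
  }
  res <- hypergeometric_enrich(query, collection, universe)
  res$p_adj <- bh_adjust(res$p)
  res[res$p_adj <= alpha, ]
}

#' Enrichment for every cell of a cohort
#'
#' @param calls A `cna_calls` object.
#' @param annotation,collection,alpha,mode,universe See [enrich_cell()].
#' @param cell_ids Cells to process (default: all called cells).
#' @return Tibble of retained terms with a leading `cell_id` column.
#' @export
enrich_cells <- function(calls, annotation, collection, alpha = 0.05,
                         mode = "any_overlap", universe = NULL,
                         cell_ids = NULL) {
  stopifnot(inherits(calls, "cna_calls"))
  cell_ids <- cell_ids %||% calls$cells$cell_id
  purrr::map(cell_ids, function(id) {
    res <- suppressWarnings(
      enrich_cell(calls$calls[calls$calls$cell_id == id, ], annotation,
                  collection, alpha = alpha, mode = mode,
                  universe = universe)
    )
    if (nrow(res) == 0) return(NULL)
    mutate(res, cell_id = id, .before = 1)
  }) |>
    purrr::list_rbind() %||%
    tibble(cell_id = character(), term_id = character(),
           term_name = character(), term_size = integer(),
           overlap = integer(), p = numeric(), p_adj = numeric(),
           overlap_genes = list())
}
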