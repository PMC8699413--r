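#' Synthetic annotation resources on the toy genome
#'
#' Deterministic generators for the desk-scale resources the pipeline needs:
#' a gene annotation tiling the toy genome, a focal-region list with 23
#' amplification and 19 deletion entries (the size of the published
#' esophageal-cancer focal-aberration panel), and a gene-set collection with
#' a mix of genomically clustered and dispersed synthetic terms. All three
#' are pure functions of their arguments; copies are also shipped as
#' plain-text files under `inst/extdata/` (`*_synthetic.*`).
#'
#' @param genome Genome specification (default [toy_genome()]).
#' @name toy_fixtures
NULL

#' @rdname toy_fixtures
#' @param spacing Gene spacing in bp.
#' @param width Gene width in bp.
#' @export
toy_gene_annotation <- function(genome = toy_genome(), spacing = 5e5,
                                width = 1e5) {
  purrr::map2(genome$chrom, genome$length, function(ch, len) {
    starts <- seq(1e5, len - width, by = spacing)
    tibble(
      gene = sprintf("SYN_%s_%03d", sub("chr", "", ch), seq_along(starts)),
      chrom = ch, start = starts, end = starts + width
    )
  }) |> purrr::list_rbind()
}

#' @rdname toy_fixtures
#' @param annotation Gene annotation (default [toy_gene_annotation()]).
#' @export
toy_focal_regions <- function(genome = toy_genome(),
                              annotation = toy_gene_annotation(genome)) {
  n_amp <- 23
  n_del <- 19
  withr::with_seed(20210101L, {
    mk <- function(n, kind, arm) {
      ch <- sample(genome$chrom, n, replace = TRUE)
      len <- genome$length[match(ch, genome$chrom)]
      width <- stats::runif(n, 2e6, 4e6)
      start <- floor(stats::runif(n, 0, len - width) / 1e5) * 1e5
      band <- sprintf("%s%s%d%d.%d", sub("chr", "", ch), arm,
                      sample(1:3, n, TRUE), sample(1:3, n, TRUE),
                      sample(1:3, n, TRUE))
      tibble(chrom = ch, start = start, end = start + round(width),
             label = paste0(band, "_", kind, seq_len(n)), kind = kind)
    }
    regions <- bind_rows(mk(n_amp, "amplification", "q"),
                         mk(n_del, "deletion", "p"))
  })
  regions$genes <- purrr::pmap(regions[, c("chrom", "start", "end")],
                               function(chrom, start, end) {
    annotation$gene[annotation$chrom == chrom & annotation$start < end &
                      annotation$end > start]
  })
  regions
}

#' @rdname toy_fixtures
#' @param n_clustered,n_dispersed Numbers of genomically clustered and
#'   dispersed terms.
#' @param cluster_size,dispersed_size Genes per term.
#' @export
toy_gene_sets <- function(annotation = toy_gene_annotation(),
                          n_clustered = 12, n_dispersed = 8,
                          cluster_size = 30, dispersed_size = 40) {
  genes <- annotation$gene
  withr::with_seed(20210102L, {
    clustered <- purrr::map(seq_len(n_clustered), function(i) {
      at <- sample(length(genes) - cluster_size, 1)
      genes[at:(at + cluster_size - 1)]
    })
    dispersed <- purrr::map(seq_len(n_dispersed), function(i) {
      sample(genes, dispersed_size)
    })
  })
  tibble(
    term_id = sprintf("SYNGO:%04d", seq_len(n_clustered + n_dispersed)),
    term_name = c(
      sprintf("clustered locus program %d (synthetic)", seq_len(n_clustered)),
      sprintf("dispersed process %d (synthetic)", seq_len(n_dispersed))
    ),
    genes = c(clustered, dispersed)
  )
}
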