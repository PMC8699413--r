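#' Recurrence of CNAs over focal regions, stratified by cohort group
#'
#' Counts, for every focal region, how many distinct CTCs carry at least one
#' significant CNA overlapping it, stratified by time point and by outcome.
#' A cell contributes at most once per region and stratum. With
#' `match_kind = TRUE` (default) a call only counts towards an
#' `amplification` region if it is a gain (copy number > 2), and towards a
#' `deletion` region if it is a loss.
#'
#' @param calls A `cna_calls` object or a calls tibble with `cell_id`,
#'   `chrom`, `start`, `end`, `copy_number`.
#' @param regions Focal-region tibble from [load_region_list()] (needs
#'   `chrom`, `start`, `end`, `label`, `kind`).
#' @param metadata Cohort metadata (`cell_id`, `time_point`, `outcome`,
#'   `cell_class`); only CTC records are counted.
#' @param match_kind Require call direction to match the region kind.
#' @param min_overlap Minimum overlap in bp for a call to count (default 1).
#'
#' @return An object of class `recurrence_matrix`: a long tibble `label`,
#'   `kind`, `stratum_type` (`"time_point"` or `"outcome"`), `stratum`,
#'   `count`, `total` (stratum size).
#' @export
region_recurrence <- function(calls, regions, metadata, match_kind = TRUE,
                              min_overlap = 1) {
  call_tbl <- if (inherits(calls, "cna_calls")) calls$calls else calls
  assert_cols(regions, c("chrom", "start", "end", "label", "kind"), "regions")
  ctc <- metadata[metadata$cell_class == "CTC", ]
  strata <- bind_rows(
    tibble(stratum_type = "time_point", stratum = ctc$time_point,
           cell_id = ctc$cell_id),
    tibble(stratum_type = "outcome", stratum = ctc$outcome,
           cell_id = ctc$cell_id)
  )
  totals <- strata |>
    count(.data$stratum_type, .data$stratum, name = "total")

  hits <- purrr::pmap(regions[, c("chrom", "start", "end", "label", "kind")],
                      function(chrom, start, end, label, kind) {
    sub <- call_tbl[call_tbl$chrom == chrom &
                      pmin(call_tbl$end, end) -
                        pmax(call_tbl$start, start) >= min_overlap, ]
    if (match_kind && nrow(sub) > 0) {
      sub <- if (kind == "amplification") sub[sub$copy_number > 2, ] else
        sub[sub$copy_number < 2, ]
    }
    tibble(label = label, kind = kind,
           cell_id = intersect(unique(sub$cell_id), ctc$cell_id))
  }) |> purrr::list_rbind()

  grid_rows <- tidyr::crossing(regions[, c("label", "kind")], totals)
  counts <- hits |>
    inner_join(strata, by = "cell_id", relationship = "many-to-many") |>
    distinct(.data$label, .data$stratum_type, .data$stratum, .data$cell_id) |>
    count(.data$label, .data$stratum_type, .data$stratum, name = "count")
  out <- grid_rows |>
    left_join(counts, by = c("label", "stratum_type", "stratum")) |>
    mutate(count = tidyr::replace_na(.data$count, 0L)) |>
    arrange(match(.data$label, regions$label), .data$stratum_type,
            .data$stratum) |>
    select("label", "kind", "stratum_type", "stratum", "count", "total")
  class(out) <- c("recurrence_matrix", class(out))
  out
}

#' Recurrence of CNAs over genes
#'
#' As [region_recurrence()] with genes of an annotation as rows; direction is
#' not constrained (`match_kind` has no meaning for a bare gene), and genes
#' with missing coordinates are skipped with a warning.
#'
#' @param calls A `cna_calls` object or calls tibble.
#' @param gene_annotation Tibble `gene`, `chrom`, `start`, `end`.
#' @param metadata Cohort metadata.
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return A `recurrence_matrix` tibble with `label` = gene (column `kind`
#'   set to `"gene"`).
#' @export
gene_recurrence <- function(calls, gene_annotation, metadata,
                            min_overlap = 1) {
  assert_cols(gene_annotation, c("gene", "chrom", "start", "end"),
              "gene_annotation")
  bad <- is.na(gene_annotation$start) | is.na(gene_annotation$end)
  if (any(bad)) {
    warn(paste0("skipping ", sum(bad), " gene(s) with missing coordinates"))
    gene_annotation <- gene_annotation[!bad, ]
  }
  regions <- tibble(
    chrom = gene_annotation$chrom, start = gene_annotation$start,
    end = gene_annotation$end, label = gene_annotation$gene, kind = "gene"
  )
  region_recurrence(calls, regions, metadata, match_kind = FALSE,
                    min_overlap = min_overlap)
}

#' Stratified recurrence percentages
#'
#' `100 * count / total` per row, rounded half away from zero to one
#' decimal, matching the convention of published per-stratum CTC
#' percentages (e.g. 8 of 29 cells -> 27.6). Strata with zero total get
#' `NA`, not 0.
#'
#' @param matrix A `recurrence_matrix` from [region_recurrence()] or
#'   [gene_recurrence()].
#' @return The input tibble with a `percent` column added.
#' @export
stratified_percentages <- function(matrix) {
  mutate(matrix, percent = ifelse(.data$total > 0,
                                  round_half_away(100 * .data$count /
                                                    .data$total, 1),
                                  NA_real_))
}

#' Heatmap of a recurrence matrix
#'
#' @param object A `recurrence_matrix`.
#' @param ... Unused.
#' @return A ggplot object (tiles: region by stratum, fill = count).
#' @method autoplot recurrence_matrix
#' @export
autoplot.recurrence_matrix <- function(object, ...) {
  df <- mutate(object,
               stratum = paste(.data$stratum_type, .data$stratum, sep = ": "))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum, y = .data$label,
                                   fill = .data$count)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 2.5) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "cells") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
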