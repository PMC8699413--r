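#' Aberrant bin set of a cell
#'
#' Converts a cell's significant CNA calls to the set of genome bins whose
#' midpoint lies inside a call, each tagged with its direction (`gain` for
#' copy number > 2, `loss` for < 2).
#'
#' @param calls Tibble of one cell's calls (`chrom`, `start`, `end`,
#'   `copy_number`), e.g. one cell's rows of `tidy(call_cnas(...))`.
#' @param grid Bin grid.
#' @return Tibble with columns `bin` (0-based) and `direction`.
#' @export
aberrant_bin_set <- function(calls, grid) {
  if (nrow(calls) == 0) {
    return(tibble(bin = integer(), direction = character()))
  }
  purrr::pmap(calls[, c("chrom", "start", "end", "copy_number")],
              function(chrom, start, end, copy_number) {
    tibble(bin = bins_overlapping(grid, chrom, start, end),
           direction = if (copy_number > 2) "gain" else "loss")
  }) |>
    purrr::list_rbind() |>
    distinct() |>
    arrange(.data$bin)
}

#' Jaccard index between two aberrant bin sets
#'
#' `|A intersect B| / |A union B|`. In `status` mode the sets are bare bin
#' indices (a shared aberration counts whatever its direction); in `signed`
#' mode the elements are (bin, direction) pairs. Two empty sets give 1: two
#' fully diploid profiles have identical (empty) aberration content, which
#' is the reading under which a Jaccard index of 1 means complete overlap
#' with a normal diploid genome.
#'
#' @param a,b Aberrant bin sets from [aberrant_bin_set()] over the same grid.
#' @param direction_mode `"status"` (default) or `"signed"`.
#' @return A number in `[0, 1]`.
#' @export
jaccard_index <- function(a, b, direction_mode = c("status", "signed")) {
  direction_mode <- match.arg(direction_mode)
  key <- function(s) {
    if (direction_mode == "status") unique(s$bin) else
      unique(paste(s$bin, s$direction))
  }
  ka <- key(a)
  kb <- key(b)
  if (length(ka) == 0 && length(kb) == 0) return(1)
  length(intersect(ka, kb)) / length(union(ka, kb))
}

#' Jaccard indexes of one CTC against its reference leukocytes
#'
#' @param cell Aberrant bin set of the CTC.
#' @param refs Named list of aberrant bin sets, one per reference leukocyte
#'   (non-empty; the study design uses five).
#' @param aggregate `"mean"` (default), `"median"`, or `"all"` (no summary,
#'   keep one row per reference).
#' @param direction_mode Passed to [jaccard_index()].
#' @return Tibble with columns `leukocyte_id` and `ji`; unless
#'   `aggregate = "all"`, the summary is attached as attribute `summary_ji`
#'   and also returned by [summary()].
#' @export
ji_against_references <- function(cell, refs,
                                  aggregate = c("mean", "median", "all"),
                                  direction_mode = "status") {
  aggregate <- match.arg(aggregate)
  if (length(refs) == 0) stop_ctcna("refs must be non-empty")
  ids <- names(refs) %||% paste0("ref", seq_along(refs))
  per_ref <- tibble(
    leukocyte_id = ids,
    ji = unname(purrr::map_dbl(refs, jaccard_index, a = cell,
                               direction_mode = direction_mode))
  )
  if (aggregate != "all") {
    attr(per_ref, "summary_ji") <-
      if (aggregate == "mean") mean(per_ref$ji) else
        stats::median(per_ref$ji)
  }
  per_ref
}

#' Jaccard genomic-imbalance table for a cohort
#'
#' Scores every CTC against reference leukocytes: patient-matched
#' leukocytes when the patient has at least `min_refs`, otherwise the cohort
#' leukocyte pool (first `n_refs` cells). Leukocyte aberration sets come
#' from the same calling workflow as the CTCs.
#'
#' @param calls A `cna_calls` object covering CTCs and leukocytes.
#' @param metadata Cohort metadata tibble (`cell_id`, `patient_id`,
#'   `time_point`, `outcome`, `cell_class`).
#' @param grid Bin grid.
#' @param n_refs References per CTC (default 5).
#' @param aggregate,direction_mode See [ji_against_references()].
#' @param matched Use patient-matched leukocytes when available (default
#'   `TRUE`).
#' @return Tibble with one row per CTC (`cell_id`, `patient_id`,
#'   `time_point`, `outcome`, `summary_ji`, and list-column `per_reference`),
#'   or one row per CTC-leukocyte pair when `aggregate = "all"` (`ji` column
#'   instead of `summary_ji`).
#' @export
ji_table <- function(calls, metadata, grid, n_refs = 5,
                     aggregate = c("mean", "median", "all"),
                     direction_mode = "status", matched = TRUE) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(calls, "cna_calls"))
  assert_cols(metadata, c("cell_id", "patient_id", "time_point", "outcome",
                          "cell_class"), "metadata")
  call_tbl <- calls$calls
  sets <- purrr::map(stats::setNames(nm = calls$cells$cell_id), function(id) {
    aberrant_bin_set(call_tbl[call_tbl$cell_id == id, ], grid)
  })
  leuko_meta <- metadata[metadata$cell_class == "leukocyte", ]
  ctc_meta <- metadata[metadata$cell_class == "CTC", ]
  if (nrow(leuko_meta) == 0) stop_ctcna("no leukocyte records in metadata")

  rows <- purrr::pmap(ctc_meta[, c("cell_id", "patient_id", "time_point",
                                   "outcome")],
                      function(cell_id, patient_id, time_point, outcome) {
    own <- leuko_meta$cell_id[leuko_meta$patient_id == patient_id]
    ref_ids <- if (matched && length(own) >= n_refs) own[seq_len(n_refs)] else
      leuko_meta$cell_id[seq_len(min(n_refs, nrow(leuko_meta)))]
    per_ref <- ji_against_references(sets[[cell_id]], sets[ref_ids],
                                     aggregate = aggregate,
                                     direction_mode = direction_mode)
    tibble(cell_id = cell_id, patient_id = patient_id,
           time_point = time_point, outcome = outcome,
           summary_ji = attr(per_ref, "summary_ji") %||% NA_real_,
           per_reference = list(per_ref))
  })
  out <- purrr::list_rbind(rows)
  if (aggregate == "all") {
    out <- out |>
      select(-"summary_ji") |>
      tidyr::unnest("per_reference")
  }
  out
}
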