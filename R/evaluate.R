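#' Benchmark called CNAs against ground truth
#'
#' Event-level recall and precision with breakpoint tolerance: a truth CNA
#' counts as recovered when a call of the same cell and direction (gain vs
#' loss) covers at least `min_overlap_frac` of its bins; a call counts as a
#' true positive when at least `min_overlap_frac` of its bins lie inside
#' truth CNAs of the same direction.
#'
#' @param calls A `cna_calls` object or calls tibble (`cell_id`, `chrom`,
#'   `start`, `end`, `copy_number`).
#' @param truth Truth tibble (`cell_id`, `chrom`, `start`, `end`,
#'   `copy_number`).
#' @param grid Bin grid.
#' @param min_overlap_frac Minimum fractional bin overlap (default 0.5).
#' @return One-row tibble: `n_truth`, `n_calls`, `recall`, `precision`.
#' @export
evaluate_calls <- function(calls, truth, grid, min_overlap_frac = 0.5) {
  call_tbl <- if (inherits(calls, "cna_calls")) calls$calls else calls
  dir_of <- function(cn) ifelse(cn > 2, "gain", "loss")
  event_bins <- function(df) {
    purrr::pmap(df[, c("chrom", "start", "end")],
                function(chrom, start, end)
                  bins_overlapping(grid, chrom, start, end))
  }
  tb <- event_bins(truth)
  cb <- event_bins(call_tbl)
  tdir <- dir_of(truth$copy_number)
  cdir <- dir_of(call_tbl$copy_number)

  hit_frac <- function(bins, others) {
    if (length(others) == 0 || length(bins) == 0) return(0)
    length(intersect(bins, unique(unlist(others)))) / length(bins)
  }
  recalled <- vapply(seq_len(nrow(truth)), function(i) {
    same <- which(call_tbl$cell_id == truth$cell_id[i] & cdir == tdir[i])
    hit_frac(tb[[i]], cb[same]) >= min_overlap_frac
  }, logical(1))
  true_pos <- vapply(seq_len(nrow(call_tbl)), function(i) {
    same <- which(truth$cell_id == call_tbl$cell_id[i] & tdir == cdir[i])
    hit_frac(cb[[i]], tb[same]) >= min_overlap_frac
  }, logical(1))
  tibble(
    n_truth = nrow(truth),
    n_calls = nrow(call_tbl),
    recall = if (nrow(truth) > 0) mean(recalled) else NA_real_,
    precision = if (nrow(call_tbl) > 0) mean(true_pos) else NA_real_
  )
}
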