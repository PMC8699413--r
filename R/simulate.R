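#' Default 11-patient cohort layout
#'
#' Per-patient CTC counts at the three blood-draw time points (A: before
#' therapy, B: after neoadjuvant therapy, C: after surgery) for a cohort of
#' 11 locally advanced esophageal cancer patients. Column totals are 20 (A),
#' 27 (B) and 10 (C) CTCs, split 15/5, 13/14 and 1/9 between relapsed and
#' disease-free patients, i.e. 57 CTCs in all, 29 from relapsed and 28 from
#' disease-free patients. The study cohort defines only these stratum totals;
#' the split across individual patients is a fixed design choice.
#'
#' @return A tibble with columns `patient_id`, `outcome`
#'   (`"relapsed"`/`"disease_free"`), `n_A`, `n_B`, `n_C`.
#' @export
default_patients <- function() {
  tibble(
    patient_id = sprintf("P%02d", 1:11),
    outcome = rep(c("relapsed", "disease_free"), c(5, 6)),
    n_A = c(4, 4, 3, 2, 2, 1, 1, 1, 1, 1, 0),
    n_B = c(3, 3, 3, 2, 2, 3, 3, 2, 2, 2, 2),
    n_C = c(1, 0, 0, 0, 0, 2, 2, 2, 1, 1, 1)
  )
}

#' Specify a synthetic single-cell cohort
#'
#' Collects every knob of the cohort simulator: the patient table, the
#' per-outcome aberrant genome fractions, the noise model of WGA-amplified
#' low-pass sequencing and the recurrent WGA-bias loci shared by all cells.
#'
#' @param patients Tibble with columns `patient_id`, `outcome`, `n_A`, `n_B`,
#'   `n_C` (CTCs per time point); defaults to [default_patients()].
#' @param aberrant_fraction Named numeric: target fraction of the genome
#'   covered by CNAs for CTCs of each outcome group. Relapsed-patient CTCs
#'   carry more aberrant genome than disease-free ones by default.
#' @param timepoint_effect Named numeric multiplier on the aberrant fraction
#'   per time point; the default attenuates post-neoadjuvant (B) cells,
#'   emulating the reduced genomic imbalance seen after therapy.
#' @param cn_weights Named numeric weights over aberrant integer copy-number
#'   states (names are copy numbers, never 2).
#' @param arm_prob Probability that a simulated CNA is arm-scale (half a
#'   chromosome) rather than focal.
#' @param focal_meanlog,focal_sdlog Log-normal parameters of focal event
#'   length in bins (clipped to `[10, 80]`).
#' @param n_reference_leukocytes Leukocytes simulated per patient (default 5,
#'   the number each CTC is scored against).
#' @param depth_per_bin Expected read count per bin at copy number 2.
#' @param dispersion Negative-binomial dispersion `phi` (variance
#'   `mu + phi * mu^2`).
#' @param dropout_rate Per-bin probability that WGA locus bias multiplies the
#'   count by a sub-unit factor.
#' @param n_artifact_loci,artifact_bins,artifact_multiplier Recurrent
#'   WGA-bias loci: `n_artifact_loci` intervals of `artifact_bins` bins drawn
#'   once per cohort and over-amplified by `artifact_multiplier` in every
#'   cell (CTCs and leukocytes alike). These emulate the locus-specific bias
#'   of single-cell WGA that makes leukocyte profiles near- but not exactly
#'   diploid; set `n_artifact_loci = 0` for bias-free counts.
#'
#' @return An object of class `cohort_spec` (a named list).
#' @export
cohort_spec <- function(patients = default_patients(),
                        aberrant_fraction = c(relapsed = 0.4, disease_free = 0.1),
                        timepoint_effect = c(A = 1, B = 0.6, C = 1),
                        cn_weights = c(`0` = 0.05, `1` = 0.25, `3` = 0.5, `4` = 0.2),
                        arm_prob = 0.5,
                        focal_meanlog = log(40),
                        focal_sdlog = 0.5,
                        n_reference_leukocytes = 5,
                        depth_per_bin = 100,
                        dispersion = 0.05,
                        dropout_rate = 0.02,
                        n_artifact_loci = 3,
                        artifact_bins = 12,
                        artifact_multiplier = 1.7) {
  assert_cols(patients, c("patient_id", "outcome", "n_A", "n_B", "n_C"),
              "patients")
  if (anyDuplicated(patients$patient_id)) {
    stop_ctcna("patient_id values must be unique")
  }
  if (!all(patients$outcome %in% c("relapsed", "disease_free"))) {
    stop_ctcna("outcome must be 'relapsed' or 'disease_free'")
  }
  counts <- unlist(patients[, c("n_A", "n_B", "n_C")])
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_ctcna("per-time-point CTC counts must be non-negative integers")
  }
  if (any(aberrant_fraction < 0 | aberrant_fraction > 1)) {
    stop_ctcna("aberrant_fraction values must lie in [0, 1]")
  }
  if (any(as.integer(names(cn_weights)) == 2L)) {
    stop_ctcna("cn_weights must not include the neutral state 2")
  }
  if (dispersion <= 0) stop_ctcna("dispersion must be > 0")
  if (dropout_rate < 0 || dropout_rate > 1) {
    stop_ctcna("dropout_rate must lie in [0, 1]")
  }
  if (n_reference_leukocytes < 1) {
    stop_ctcna("n_reference_leukocytes must be >= 1")
  }
  structure(
    list(
      patients = patients,
      aberrant_fraction = aberrant_fraction,
      timepoint_effect = timepoint_effect,
      cn_weights = cn_weights,
      arm_prob = arm_prob,
      focal_meanlog = focal_meanlog,
      focal_sdlog = focal_sdlog,
      n_reference_leukocytes = n_reference_leukocytes,
      depth_per_bin = depth_per_bin,
      dispersion = dispersion,
      dropout_rate = dropout_rate,
      n_artifact_loci = n_artifact_loci,
      artifact_bins = artifact_bins,
      artifact_multiplier = artifact_multiplier
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  n_ctc <- sum(x$patients$n_A + x$patients$n_B + x$patients$n_C)
  cat("<cohort_spec> ", nrow(x$patients), " patients, ", n_ctc, " CTCs, ",
      x$n_reference_leukocytes, " reference leukocytes/patient\n", sep = "")
  cat("  aberrant fraction:",
      paste(names(x$aberrant_fraction), x$aberrant_fraction,
            sep = "=", collapse = ", "), "\n")
  cat("  depth/bin:", x$depth_per_bin, " dispersion:", x$dispersion,
      " dropout:", x$dropout_rate, "\n")
  invisible(x)
}

# per-bin copy number implied by a set of truth CNAs (2 where none covers
# the bin midpoint); rejects conflicting overlaps
truth_to_bin_cn <- function(grid, truth) {
  cn <- rep(2L, nrow(grid))
  if (is.null(truth) || nrow(truth) == 0) return(cn)
  assert_cols(truth, c("chrom", "start", "end", "copy_number"), "truth")
  for (i in seq_len(nrow(truth))) {
    idx <- bins_overlapping(grid, truth$chrom[i], truth$start[i], truth$end[i]) + 1L
    clash <- idx[cn[idx] != 2L & cn[idx] != truth$copy_number[i]]
    if (length(clash) > 0) {
      stop_ctcna("overlapping truth CNAs with conflicting copy numbers at ",
                 truth$chrom[i], ":", truth$start[i], "-", truth$end[i])
    }
    cn[idx] <- as.integer(truth$copy_number[i])
  }
  cn
}

#' Simulate one cell's bin counts
#'
#' Draws a negative-binomial count for every bin with mean
#' `depth_per_bin * cn / 2`, where `cn` is the ground-truth copy number
#' covering the bin midpoint (2 where no truth CNA does). With probability
#' `dropout_rate` a bin's count is shrunk by a uniform sub-unit factor,
#' emulating random WGA locus bias. A zero mean (copy number 0) degenerates
#' to a count of exactly 0.
#'
#' @param grid A bin grid from [build_bin_grid()].
#' @param truth Tibble of ground-truth CNAs (`chrom`, `start`, `end`,
#'   `copy_number`); may be empty or `NULL` for a diploid cell.
#' @param depth_per_bin Expected count per bin at copy number 2.
#' @param dispersion Negative-binomial dispersion (`> 0`).
#' @param dropout_rate Per-bin dropout probability in `[0, 1]`.
#' @param seed Integer seed; identical seeds give identical counts.
#' @param bias Optional multiplicative bias per bin (e.g. recurrent WGA
#'   artifact loci); defaults to 1 everywhere.
#'
#' @return Integer vector of counts, one per bin of `grid`.
#' @export
simulate_cell_counts <- function(grid, truth = NULL, depth_per_bin = 100,
                                 dispersion = 0.05, dropout_rate = 0.02,
                                 seed = 1L, bias = NULL) {
  cn <- truth_to_bin_cn(grid, truth)
  n <- nrow(grid)
  bias <- bias %||% rep(1, n)
  withr::local_seed(seed)
  mu <- depth_per_bin * cn / 2 * bias
  counts <- integer(n)
  pos <- mu > 0
  counts[pos] <- stats::rnbinom(sum(pos), mu = mu[pos], size = 1 / dispersion)
  if (dropout_rate > 0) {
    hit <- stats::runif(n) < dropout_rate
    counts[hit] <- as.integer(floor(counts[hit] * stats::runif(sum(hit), 0, 0.5)))
  }
  counts
}

#' Draw ground-truth CNAs covering a target genome fraction
#'
#' Samples non-overlapping arm-scale and focal events (mixture controlled by
#' `arm_prob` and the copy-state weights of the cohort specification) until
#' the covered bin fraction reaches `target_fraction`; the final event may
#' overshoot.
#' Randomness comes from the current RNG state.
#'
#' @param grid Bin grid.
#' @param target_fraction Target aberrant genome fraction in `[0, 1]`.
#' @param spec A [cohort_spec()] supplying the event-length and copy-state
#'   parameters.
#' @return Truth tibble (`chrom`, `start`, `end`, `copy_number`).
#' @export
sample_truth_cnas <- function(grid, target_fraction, spec = cohort_spec()) {
  n_bins <- nrow(grid)
  target_bins <- target_fraction * n_bins
  if (target_bins < 1) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  copy_number = integer()))
  }
  chroms <- unique(grid$chrom)
  covered <- rep(FALSE, n_bins)
  out <- list()
  cn_states <- as.integer(names(spec$cn_weights))
  tries <- 0
  while (sum(covered) < target_bins && tries < 500) {
    tries <- tries + 1
    ch <- sample(chroms, 1)
    ch_bins <- which(grid$chrom == ch)
    n_ch <- length(ch_bins)
    if (stats::runif(1) < spec$arm_prob) {
      half <- floor(n_ch / 2)
      idx <- if (stats::runif(1) < 0.5) ch_bins[seq_len(half)] else
        ch_bins[(half + 1):n_ch]
    } else {
      len <- round(stats::rlnorm(1, spec$focal_meanlog, spec$focal_sdlog))
      len <- max(10, min(80, len, n_ch))
      at <- sample(n_ch - len + 1, 1)
      idx <- ch_bins[at:(at + len - 1)]
    }
    if (any(covered[idx])) next
    covered[idx] <- TRUE
    cn <- sample(cn_states, 1, prob = spec$cn_weights)
    out[[length(out) + 1]] <- tibble(
      chrom = ch,
      start = grid$start[idx[1]],
      end = grid$end[idx[length(idx)]],
      copy_number = cn
    )
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  copy_number = integer()))
  }
  purrr::list_rbind(out) |> arrange(match(.data$chrom, chroms), .data$start)
}

#' Simulate a full single-cell cohort
#'
#' Generates one bin-count profile per requested CTC plus
#' `n_reference_leukocytes` diploid leukocytes per patient. CTC ground-truth
#' CNAs are drawn so the realized aberrant genome fraction matches the
#' per-group target within sampling error; leukocyte truth is empty. A small
#' set of recurrent WGA-bias loci (see [cohort_spec()]) is shared by every
#' cell. The whole cohort is a deterministic function of `spec` and `seed`.
#'
#' @param spec A [cohort_spec()].
#' @param grid A bin grid from [build_bin_grid()].
#' @param seed Integer seed.
#'
#' @return A list with elements
#'   \describe{
#'     \item{counts}{wide tibble: `chrom`, `start`, `end`, then one integer
#'       column per `cell_id`;}
#'     \item{metadata}{tibble with `cell_id`, `patient_id`, `time_point`,
#'       `outcome`, `cell_class`, `phenotype`;}
#'     \item{truth}{tibble of ground-truth CNAs with a `cell_id` column
#'       (empty for leukocytes);}
#'     \item{artifact_bins}{0-based indices of the recurrent WGA-bias bins.}
#'   }
#' @export
simulate_cohort <- function(spec, grid, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::local_seed(seed)
  n_bins <- nrow(grid)

  bias <- rep(1, n_bins)
  artifact_idx <- integer(0)
  if (spec$n_artifact_loci > 0) {
    starts <- sample(n_bins - spec$artifact_bins, spec$n_artifact_loci)
    for (s in starts) {
      idx <- s:(s + spec$artifact_bins - 1)
      bias[idx] <- spec$artifact_multiplier
      artifact_idx <- c(artifact_idx, idx - 1L)
    }
  }

  cells <- tidyr::pivot_longer(
    spec$patients, cols = c("n_A", "n_B", "n_C"),
    names_to = "time_point", names_prefix = "n_", values_to = "n_ctc"
  ) |>
    rowwise() |>
    reframe(
      patient_id = .data$patient_id, outcome = .data$outcome,
      time_point = .data$time_point,
      rank = seq_len(.data$n_ctc)
    ) |>
    mutate(
      cell_id = paste0(.data$patient_id, "_", .data$time_point, "_CTC",
                       .data$rank),
      cell_class = "CTC",
      phenotype = sample(c("E", "SM", "mixed"), dplyr::n(),
                         replace = TRUE, prob = c(0.6, 0.2, 0.2))
    ) |>
    select(-"rank")

  leuko <- spec$patients |>
    rowwise() |>
    reframe(
      patient_id = .data$patient_id, outcome = .data$outcome,
      rank = seq_len(spec$n_reference_leukocytes)
    ) |>
    mutate(
      time_point = NA_character_,
      cell_id = paste0(.data$patient_id, "_WBC", .data$rank),
      cell_class = "leukocyte",
      phenotype = NA_character_
    ) |>
    select(-"rank")

  metadata <- bind_rows(
    cells[, c("cell_id", "patient_id", "time_point", "outcome", "cell_class",
              "phenotype")],
    leuko[, c("cell_id", "patient_id", "time_point", "outcome", "cell_class",
              "phenotype")]
  )

  cell_seeds <- sample.int(.Machine$integer.max - 1L, nrow(metadata))
  counts <- matrix(0L, nrow = n_bins, ncol = nrow(metadata))
  truth_list <- list()
  for (i in seq_len(nrow(metadata))) {
    row <- metadata[i, ]
    if (row$cell_class == "CTC") {
      frac <- spec$aberrant_fraction[[row$outcome]] *
        spec$timepoint_effect[[row$time_point]]
      truth <- sample_truth_cnas(grid, frac, spec)
      if (nrow(truth) > 0) {
        truth_list[[length(truth_list) + 1]] <-
          mutate(truth, cell_id = row$cell_id, .before = 1)
      }
    } else {
      truth <- NULL
    }
    counts[, i] <- simulate_cell_counts(
      grid, truth, spec$depth_per_bin, spec$dispersion, spec$dropout_rate,
      seed = cell_seeds[i], bias = bias
    )
  }
  colnames(counts) <- metadata$cell_id

  truth <- if (length(truth_list) > 0) purrr::list_rbind(truth_list) else
    tibble(cell_id = character(), chrom = character(), start = numeric(),
           end = numeric(), copy_number = integer())

  counts_tbl <- bind_cols(grid[, c("chrom", "start", "end")],
                          as_tibble(counts))
  list(counts = counts_tbl, metadata = metadata, truth = truth,
       artifact_bins = sort(unique(artifact_idx)))
}

#' Realized aberrant genome fraction of ground-truth CNAs
#'
#' @param truth Truth tibble with `cell_id` column (as from
#'   [simulate_cohort()]).
#' @param grid The bin grid the truth was drawn on.
#' @param cell_ids Cells to report (defaults to those present in `truth`).
#' @return Tibble with `cell_id` and `truth_fraction` (fraction of bins whose
#'   midpoint lies inside a truth CNA).
#' @export
truth_aberrant_fraction <- function(truth, grid, cell_ids = NULL) {
  cell_ids <- cell_ids %||% unique(truth$cell_id)
  n_bins <- nrow(grid)
  purrr::map(cell_ids, function(id) {
    tr <- truth[truth$cell_id == id, ]
    bins <- unique(unlist(purrr::pmap(
      tr[, c("chrom", "start", "end")],
      function(chrom, start, end) bins_overlapping(grid, chrom, start, end)
    )))
    tibble(cell_id = id, truth_fraction = length(bins) / n_bins)
  }) |> purrr::list_rbind()
}
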