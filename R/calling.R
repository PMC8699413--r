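#' Normalize a cell's bin counts to copy-number ratios
#'
#' Scales counts by their median over valid bins so that a diploid genome
#' sits at ratio 1. When `gc_correct` is `TRUE` and the grid carries a `gc`
#' column, a loess-smoothed GC trend is divided out first and bins with
#' extreme GC (< 0.25 or > 0.75) are masked invalid.
#'
#' @param counts Integer vector of bin counts (one per grid bin).
#' @param grid Bin grid from [build_bin_grid()].
#' @param gc_correct Divide out a smoothed GC trend before median scaling.
#' @param mask Optional logical vector of bins to exclude (e.g. bins
#'   unmappable in the reference); `TRUE` = excluded.
#'
#' @return A tibble with columns `bin`, `chrom`, `ratio`, `valid`.
#' @export
normalize_counts <- function(counts, grid, gc_correct = FALSE, mask = NULL) {
  if (length(counts) != nrow(grid)) {
    stop_ctcna("counts length (", length(counts),
               ") does not match grid (", nrow(grid), " bins)")
  }
  if (all(counts == 0)) stop_ctcna("cell has no signal (all-zero counts)")
  valid <- rep(TRUE, nrow(grid))
  if (!is.null(mask)) valid <- valid & !mask
  x <- as.numeric(counts)
  if (gc_correct && !is.null(grid$gc)) {
    valid <- valid & grid$gc >= 0.25 & grid$gc <= 0.75
    fit <- stats::loess(x[valid] ~ grid$gc[valid], span = 0.5, degree = 2)
    trend <- stats::predict(fit, newdata = grid$gc)
    trend[is.na(trend) | trend <= 0] <- 1
    trend <- trend / stats::median(trend[valid])
    x <- x / trend
  }
  med <- stats::median(x[valid])
  if (med <= 0) stop_ctcna("cell has no signal (zero median count)")
  tibble(bin = grid$bin, chrom = grid$chrom, ratio = x / med, valid = valid)
}

# replace isolated outlier bins (WGA dropout spikes) by the median of a
# centred window, as CNA segmenters conventionally do before change-point
# detection; operates on the log2 scale
smooth_outliers <- function(y, window = 7, k = 3) {
  n <- length(y)
  if (n < window) return(y)
  rmed <- stats::runmed(y, window, endrule = "median")
  sigma <- stats::median(abs(diff(y))) / (sqrt(2) * 0.6745)
  if (!is.finite(sigma) || sigma == 0) return(y)
  out <- abs(y - rmed) > k * sigma
  y[out] <- rmed[out]
  y
}

# penalized least-squares change-point detection by optimal partitioning on
# y; returns start indices (1-based, within y) of each segment
optimal_partition <- function(y, penalty, min_bins) {
  n <- length(y)
  min_bins <- as.integer(min_bins)
  if (n < 2 * min_bins) return(1L)
  cs <- c(0, cumsum(y))
  cs2 <- c(0, cumsum(y^2))
  seg_cost <- function(i, j) { # 1-based inclusive, vectorized over i
    len <- j - i + 1
    s <- cs[j + 1] - cs[i]
    (cs2[j + 1] - cs2[i]) - s^2 / len
  }
  f <- rep(Inf, n + 1)
  f[1] <- -penalty
  prev <- integer(n + 1)
  for (j in min_bins:n) {
    cand <- if (j < 2L * min_bins) 0L else
      c(0L, seq.int(min_bins, j - min_bins))
    vals <- f[cand + 1] + seg_cost(cand + 1, j) + penalty
    k <- which.min(vals)
    f[j + 1] <- vals[k]
    prev[j + 1] <- cand[k]
  }
  # backtrack
  bps <- integer(0)
  at <- n
  while (at > 0) {
    bps <- c(prev[at + 1], bps)
    at <- prev[at + 1]
  }
  bps + 1L
}

#' Segment a ratio profile into constant-copy-number runs
#'
#' Change-point detection on `log2(ratio + 1e-6)` per chromosome, using
#' penalized least squares solved exactly by optimal partitioning. Isolated
#' outlier bins (WGA dropout spikes) are first pulled to a running median,
#' the conventional pre-smoothing of read-depth segmenters; segment medians
#' are still computed from the unsmoothed ratios. Every
#' segment has at least `min_bins` bins; segments tile the valid bins of
#' each chromosome. A chromosome with fewer than `min_bins` valid bins is
#' returned as a single segment flagged `short = TRUE`.
#'
#' @param profile Ratio profile from [normalize_counts()].
#' @param penalty Change-point penalty, or `"auto"` for a BIC-style default
#'   `2 * sigma^2 * log(n)` with `sigma` estimated from median absolute
#'   successive differences.
#' @param min_bins Minimum bins per segment (`>= 2`, default 5).
#'
#' @return Tibble of segments: `chrom`, `start_bin`, `end_bin` (half-open,
#'   positions within the grid's 0-based bin index), `n_bins`,
#'   `median_ratio`, `bins` (list-column of member 0-based bin indices),
#'   `short`.
#' @export
segment_profile <- function(profile, penalty = "auto", min_bins = 5) {
  if (min_bins < 2) stop_ctcna("min_bins must be >= 2")
  prof <- profile[profile$valid, ]
  y_all <- log2(prof$ratio + 1e-6)
  if (identical(penalty, "auto")) {
    sigma <- stats::median(abs(diff(y_all))) / (sqrt(2) * 0.6745)
    penalty <- 2 * sigma^2 * log(length(y_all))
    if (!is.finite(penalty) || penalty <= 0) penalty <- 0.1
  }
  chroms <- unique(prof$chrom)
  acc <- vector("list", length(chroms))
  for (ci in seq_along(chroms)) {
    rows <- which(prof$chrom == chroms[ci])
    ratio <- prof$ratio[rows]
    bin <- prof$bin[rows]
    n <- length(rows)
    if (n < min_bins) {
      starts <- 1L
      short <- TRUE
    } else {
      y <- log2(ratio + 1e-6)
      starts <- optimal_partition(smooth_outliers(y), penalty, min_bins)
      short <- FALSE
    }
    ends <- c(starts[-1] - 1L, n)
    acc[[ci]] <- list(
      chrom = rep(chroms[ci], length(starts)),
      start_bin = bin[starts],
      end_bin = bin[ends] + 1L,
      n_bins = ends - starts + 1L,
      median_ratio = vapply(seq_along(starts), function(k)
        stats::median(ratio[starts[k]:ends[k]]), numeric(1)),
      bins = lapply(seq_along(starts), function(k) bin[starts[k]:ends[k]]),
      short = rep(short, length(starts))
    )
  }
  tibble(
    chrom = unlist(lapply(acc, `[[`, "chrom")),
    start_bin = unlist(lapply(acc, `[[`, "start_bin")),
    end_bin = unlist(lapply(acc, `[[`, "end_bin")),
    n_bins = unlist(lapply(acc, `[[`, "n_bins")),
    median_ratio = unlist(lapply(acc, `[[`, "median_ratio")),
    bins = do.call(c, lapply(acc, `[[`, "bins")),
    short = unlist(lapply(acc, `[[`, "short"))
  )
}

#' Integer copy number of a segment
#'
#' `max(0, round(median_ratio * ploidy))` with ties rounded half away from
#' zero (so a median ratio of 1.25 at ploidy 2 gives copy number 3).
#'
#' @param median_ratio Segment median ratio (scalar or vector).
#' @param ploidy Baseline ploidy (default 2).
#' @return Integer copy number(s).
#' @export
assign_copy_number <- function(median_ratio, ploidy = 2) {
  if (ploidy < 1) stop_ctcna("ploidy must be >= 1")
  pmax(0, as.integer(round_half_away(median_ratio * ploidy)))
}

# exact two-sided rank-sum p-value by complete enumeration of all
# choose(n1+n2, n1) group assignments; handles ties through midranks
rank_sum_exact_p <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x)
  n <- length(r)
  obs <- sum(r[seq_len(n1)])
  mid <- n1 * (n + 1) / 2
  sums <- colSums(matrix(r[utils::combn(n, n1)], nrow = n1))
  mean(abs(sums - mid) >= abs(obs - mid) - 1e-9)
}

# two-sided Mann-Whitney p: exact enumeration when both samples are small,
# normal approximation with tie correction otherwise
rank_sum_p <- function(x, y, exact_max = 8) {
  if (length(x) <= exact_max && length(y) <= exact_max) {
    rank_sum_exact_p(x, y)
  } else {
    suppressWarnings(
      stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    )
  }
}

#' Dual non-parametric significance of a putative CNA segment
#'
#' Compares a segment's bin ratios against the cell's copy-number-neutral
#' bin ratios with a two-sided Mann-Whitney test and a two-sample
#' Kolmogorov-Smirnov test. The Mann-Whitney p-value is computed by exact
#' enumeration when both samples have at most 8 values (ties included),
#' otherwise by the tie-corrected normal approximation.
#'
#' @param segment_ratios Ratios of the segment's bins (non-empty).
#' @param neutral_ratios Ratios of the cell's neutral (copy number 2) bins
#'   (non-empty).
#' @return Named list with `p_mw` and `p_ks`.
#' @export
score_segment_significance <- function(segment_ratios, neutral_ratios) {
  if (length(segment_ratios) == 0 || length(neutral_ratios) == 0) {
    stop_ctcna("both ratio vectors must be non-empty")
  }
  p_mw <- rank_sum_p(segment_ratios, neutral_ratios)
  p_ks <- suppressWarnings(
    stats::ks.test(segment_ratios, neutral_ratios)$p.value
  )
  list(p_mw = p_mw, p_ks = p_ks)
}

# pick the multiplicative rescaling that best places segment levels on
# integer copy numbers (ploidy-grid search), preferring the smallest
# adjustment: median normalization anchors the genome-wide median at CN 2,
# which is wrong for cells whose dominant aberrant state covers more than
# half the genome. Segment breakpoints are scale-invariant (log shift) and
# the rank-based tests are unaffected, so only the levels need rescaling.
diploid_rescale_factor <- function(segments, ploidy = 2, lambda = 0.05) {
  w <- segments$n_bins
  m <- segments$median_ratio
  s_grid <- 2^seq(-1, 1, by = 0.01)
  cost <- vapply(s_grid, function(s) {
    lv <- s * m * ploidy
    sum(w * (lv - round(lv))^2) / sum(w) + lambda * log2(s)^2
  }, numeric(1))
  s_grid[which.min(cost)]
}

#' Call significant CNAs for one cell
#'
#' Assigns an integer copy number to every segment, tests each non-neutral
#' segment against the cell's neutral bins with the dual Mann-Whitney /
#' Kolmogorov-Smirnov filter, keeps segments with both p-values below
#' `alpha`, and merges adjacent passing segments with equal copy number.
#' Before copy numbers are assigned, segment levels are rescaled by a
#' ploidy-grid search so that they sit on integer states even when the
#' cell's dominant aberrant state covers most of the genome (median
#' normalization alone anchors whatever state holds the genome-wide median
#' at copy number 2).
#' If the cell has no neutral segment at all (wholly aberrant genome), the
#' tests fall back to a unit-ratio reference sample and the result is
#' flagged.
#'
#' @param profile Ratio profile from [normalize_counts()].
#' @param segments Segments from [segment_profile()].
#' @param grid Bin grid (for bp coordinates).
#' @param ploidy Baseline ploidy (default 2).
#' @param alpha Significance threshold applied to both tests (default 0.05).
#'
#' @return A list of class `cell_calls`: `calls` (tibble `chrom`, `start`,
#'   `end`, `copy_number`, `p_mw`, `p_ks`, `n_bins`), `aberrant_fraction`
#'   (fraction of valid bins covered by calls), `n_segments_tested`, and
#'   `neutral_fallback` (`TRUE` when the unit-ratio reference was used).
#' @export
call_significant_cnas <- function(profile, segments, grid, ploidy = 2,
                                  alpha = 0.05) {
  s <- diploid_rescale_factor(segments, ploidy)
  if (abs(log2(s)) > 0.01) {
    profile$ratio <- profile$ratio * s
    segments$median_ratio <- segments$median_ratio * s
  }
  copy_number <- assign_copy_number(segments$median_ratio, ploidy)
  # profile rows are in grid order, so 0-based bin index + 1 = row
  neutral_bins <- unlist(segments$bins[copy_number == ploidy])
  fallback <- length(neutral_bins) == 0
  neutral_ratios <- if (fallback) rep(1, 50) else
    profile$ratio[neutral_bins + 1L]

  cand_idx <- which(copy_number != ploidy)
  tested <- length(cand_idx)
  pass <- integer(0)
  p_mw <- p_ks <- numeric(0)
  for (i in cand_idx) {
    seg_ratios <- profile$ratio[segments$bins[[i]] + 1L]
    p <- score_segment_significance(seg_ratios, neutral_ratios)
    if (p$p_mw < alpha && p$p_ks < alpha) {
      pass <- c(pass, i)
      p_mw <- c(p_mw, p$p_mw)
      p_ks <- c(p_ks, p$p_ks)
    }
  }

  n_valid <- sum(profile$valid)
  if (length(pass) == 0) {
    calls_tbl <- tibble(chrom = character(), start = numeric(),
                        end = numeric(), copy_number = integer(),
                        p_mw = numeric(), p_ks = numeric(),
                        n_bins = integer())
    ab_frac <- 0
    call_bins <- integer(0)
  } else {
    ord <- order(match(segments$chrom[pass], unique(grid$chrom)),
                 segments$start_bin[pass])
    pass <- pass[ord]
    p_mw <- p_mw[ord]
    p_ks <- p_ks[ord]
    # merge adjacent passing segments with equal copy number
    grp <- cumsum(c(1L, as.integer(
      !(segments$chrom[pass][-1] == segments$chrom[pass][-length(pass)] &
          copy_number[pass][-1] == copy_number[pass][-length(pass)] &
          segments$start_bin[pass][-1] ==
            segments$end_bin[pass][-length(pass)])
    )))
    first <- !duplicated(grp)
    last <- !duplicated(grp, fromLast = TRUE)
    calls_tbl <- tibble(
      chrom = segments$chrom[pass][first],
      start = grid$start[segments$start_bin[pass][first] + 1L],
      end = grid$end[segments$end_bin[pass][last]],
      copy_number = as.integer(copy_number[pass][first]),
      p_mw = as.numeric(tapply(p_mw, grp, max)),
      p_ks = as.numeric(tapply(p_ks, grp, max)),
      n_bins = as.integer(tapply(segments$n_bins[pass], grp, sum))
    )
    call_bins <- unlist(segments$bins[pass])
    ab_frac <- length(intersect(call_bins, profile$bin[profile$valid])) /
      n_valid
  }
  structure(
    list(calls = calls_tbl, aberrant_fraction = ab_frac,
         n_segments_tested = tested, neutral_fallback = fallback,
         call_bins = sort(call_bins)),
    class = "cell_calls"
  )
}

#' Call CNAs for every cell of a cohort
#'
#' Runs normalization, segmentation and the dual-test significance filter
#' (see [call_significant_cnas()]) on each cell column of a wide counts
#' table.
#'
#' @param counts Wide counts tibble (`chrom`, `start`, `end`, one column per
#'   cell), as produced by [simulate_cohort()] or read with [read_counts()].
#' @param grid Bin grid matching the counts rows.
#' @param penalty,min_bins Segmentation parameters (see [segment_profile()]).
#' @param ploidy,alpha Calling parameters (see [call_significant_cnas()]).
#' @param gc_correct Passed to [normalize_counts()].
#'
#' @return An object of class `cna_calls`: a list with `calls` (tibble of
#'   all calls with a `cell_id` column), `cells` (per-cell tibble with
#'   `aberrant_fraction`, `n_calls`, `n_segments_tested`,
#'   `neutral_fallback`), `call_bins` (named list of 0-based aberrant bin
#'   indices per cell) and the parameters used.
#' @export
call_cnas <- function(counts, grid, penalty = "auto", min_bins = 5,
                      ploidy = 2, alpha = 0.05, gc_correct = FALSE) {
  cell_ids <- setdiff(names(counts), c("chrom", "start", "end"))
  if (length(cell_ids) == 0) stop_ctcna("counts table has no cell columns")
  per_cell <- purrr::map(cell_ids, function(id) {
    profile <- normalize_counts(counts[[id]], grid, gc_correct = gc_correct)
    segs <- segment_profile(profile, penalty = penalty, min_bins = min_bins)
    call_significant_cnas(profile, segs, grid, ploidy = ploidy, alpha = alpha)
  })
  names(per_cell) <- cell_ids
  calls <- purrr::imap(per_cell, function(cc, id) {
    if (nrow(cc$calls) == 0) return(NULL)
    mutate(cc$calls, cell_id = id, .before = 1)
  }) |> purrr::list_rbind()
  if (is.null(calls) || nrow(calls) == 0) {
    calls <- tibble(cell_id = character(), chrom = character(),
                    start = numeric(), end = numeric(),
                    copy_number = integer(), p_mw = numeric(),
                    p_ks = numeric(), n_bins = integer())
  }
  cells <- tibble(
    cell_id = cell_ids,
    n_calls = purrr::map_int(per_cell, ~ nrow(.x$calls)),
    aberrant_fraction = purrr::map_dbl(per_cell, "aberrant_fraction"),
    n_segments_tested = purrr::map_int(per_cell, "n_segments_tested"),
    neutral_fallback = purrr::map_lgl(per_cell, "neutral_fallback")
  )
  structure(
    list(calls = calls, cells = cells,
         call_bins = purrr::map(per_cell, "call_bins"),
         params = list(penalty = penalty, min_bins = min_bins,
                       ploidy = ploidy, alpha = alpha)),
    class = "cna_calls"
  )
}

#' @export
print.cna_calls <- function(x, ...) {
  cat("<cna_calls> ", nrow(x$cells), " cells, ", nrow(x$calls),
      " significant CNAs (alpha = ", x$params$alpha, ")\n", sep = "")
  cat("  median aberrant fraction:",
      signif(stats::median(x$cells$aberrant_fraction), 3), "\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname call_cnas
#' @param x A `cna_calls` object.
#' @param ... Unused.
#' @method tidy cna_calls
#' @export
tidy.cna_calls <- function(x, ...) as_tibble(x$calls)

#' @rdname call_cnas
#' @method glance cna_calls
#' @export
glance.cna_calls <- function(x, ...) {
  tibble(
    n_cells = nrow(x$cells),
    n_calls = nrow(x$calls),
    median_aberrant_fraction = stats::median(x$cells$aberrant_fraction),
    alpha = x$params$alpha,
    min_bins = x$params$min_bins
  )
}

#' Per-bin copy-number track of called cells
#'
#' @param x A `cna_calls` object.
#' @param grid The bin grid used for calling.
#' @param cell_ids Cells to include (default all).
#' @return Long tibble `cell_id`, `bin`, `chrom`, `start`, `end`,
#'   `copy_number` (2 outside calls).
#' @export
copy_number_track <- function(x, grid, cell_ids = NULL) {
  cell_ids <- cell_ids %||% names(x$call_bins)
  purrr::map(cell_ids, function(id) {
    cn <- rep(2L, nrow(grid))
    bins <- x$call_bins[[id]]
    if (length(bins) > 0) {
      calls <- x$calls[x$calls$cell_id == id, ]
      for (i in seq_len(nrow(calls))) {
        idx <- bins_overlapping(grid, calls$chrom[i], calls$start[i],
                                calls$end[i]) + 1L
        cn[idx] <- calls$copy_number[i]
      }
    }
    bind_cols(tibble(cell_id = id), grid, tibble(copy_number = cn))
  }) |> purrr::list_rbind()
}

#' Plot per-bin copy numbers of one or more cells
#'
#' The classic low-pass single-cell CNA view: one point per bin at its
#' assigned copy number, bins inside significant CNAs highlighted.
#'
#' @param object A `cna_calls` object.
#' @param grid Bin grid used for calling.
#' @param cell_ids Cells to plot (default: first cell).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cna_calls
#' @export
autoplot.cna_calls <- function(object, grid, cell_ids = NULL, ...) {
  cell_ids <- cell_ids %||% names(object$call_bins)[1]
  track <- copy_number_track(object, grid, cell_ids) |>
    mutate(state = ifelse(.data$copy_number == 2, "neutral", "CNA"))
  ggplot2::ggplot(track, ggplot2::aes(x = .data$bin, y = .data$copy_number,
                                      colour = .data$state)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::facet_wrap(~cell_id, ncol = 1) +
    ggplot2::scale_colour_manual(values = c(neutral = "grey60",
                                            CNA = "firebrick")) +
    ggplot2::labs(x = "genome bin", y = "copy number") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
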