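#' Define a genome as an ordered set of chromosomes
#'
#' A genome specification is the coordinate universe for the whole pipeline:
#' an ordered table of chromosome names and lengths in base pairs.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Integer vector of chromosome lengths in bp (all `> 0`).
#'
#' @return A tibble with columns `chrom` and `length`.
#' @examples
#' genome_spec(c("chr1", "chr2"), c(10e6, 5e6))
#' @export
genome_spec <- function(chrom, length) {
  if (length(chrom) != length(length)) {
    stop_ctcna("chrom and length must have the same length")
  }
  if (anyDuplicated(chrom)) {
    stop_ctcna("chromosome names must be unique")
  }
  bad <- chrom[length <= 0 | is.na(length)]
  if (length(bad) > 0) {
    stop_ctcna("chromosome(s) with non-positive length: ",
               paste(bad, collapse = ", "))
  }
  tibble(chrom = as.character(chrom), length = as.numeric(length))
}

#' Desk-scale toy genome
#'
#' Eight chromosomes totalling 240 Mb, sized so that the default 100 kb bins
#' give 2,400 bins — large enough for arm-scale and focal events to coexist,
#' small enough that a full cohort analysis runs in seconds.
#'
#' @return A genome specification tibble (see [genome_spec()]).
#' @export
toy_genome <- function() {
  genome_spec(
    chrom  = paste0("chr", 1:8),
    length = c(45, 40, 35, 30, 30, 25, 20, 15) * 1e6
  )
}

#' Partition a genome into fixed-size bins
#'
#' Tiles every chromosome with windows of `bin_size` bp. Bins within a
#' chromosome are gapless and non-overlapping; the last bin of each
#' chromosome may be shorter. Bins carry a stable zero-based index `bin`
#' that is contiguous across chromosomes in genome order.
#'
#' @param genome A genome specification (see [genome_spec()]).
#' @param bin_size Window size in bp (`> 0`).
#'
#' @return A tibble with columns `bin` (0-based index), `chrom`, `start`,
#'   `end` (0-based half-open bp coordinates). The bin size is stored in the
#'   `bin_size` attribute.
#' @examples
#' grid <- build_bin_grid(toy_genome(), bin_size = 1e6)
#' nrow(grid)
#' @export
build_bin_grid <- function(genome, bin_size) {
  assert_cols(genome, c("chrom", "length"), "genome")
  if (!is.numeric(bin_size) || length(bin_size) != 1 || bin_size <= 0) {
    stop_ctcna("bin_size must be a single positive number")
  }
  bad <- genome$chrom[genome$length <= 0]
  if (length(bad) > 0) {
    stop_ctcna("chromosome(s) with non-positive length: ",
               paste(bad, collapse = ", "))
  }
  grid <- purrr::map2(genome$chrom, genome$length, function(ch, len) {
    n <- ceiling(len / bin_size)
    start <- (seq_len(n) - 1) * bin_size
    tibble(chrom = ch, start = start, end = pmin(start + bin_size, len))
  }) |>
    purrr::list_rbind() |>
    mutate(bin = dplyr::row_number() - 1L, .before = 1)
  attr(grid, "bin_size") <- bin_size
  grid
}

grid_bin_size <- function(grid) {
  attr(grid, "bin_size") %||% stats::median(grid$end - grid$start)
}

# bin index (0-based) of the bin whose interval contains each bp position
bins_overlapping <- function(grid, chrom, start, end) {
  mid <- (grid$start + grid$end) / 2
  grid$bin[grid$chrom == chrom & mid >= start & mid < end]
}
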