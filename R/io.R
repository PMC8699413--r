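#' Read and write pipeline tables
#'
#' Plain-text interchange formats used throughout the pipeline:
#' counts are TSV with `chrom`, `start`, `end` then one column per cell;
#' metadata is TSV with the cell-annotation columns of [simulate_cohort()];
#' ground-truth CNAs and calls are BED (0-based half-open), with `name` =
#' cell id and `score` = copy number, calls carrying two extra p-value
#' columns.
#'
#' @param x Table to write.
#' @param path File path.
#' @name ctcna_io
NULL

#' @rdname ctcna_io
#' @export
write_counts <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname ctcna_io
#' @export
read_counts <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname ctcna_io
#' @export
write_metadata <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname ctcna_io
#' @export
read_metadata <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = "c"))
}

#' @rdname ctcna_io
#' @export
export_truth <- function(x, path) {
  header <- "#chrom\tstart\tend\tcell_id\tcopy_number"
  lines <- if (nrow(x) > 0) {
    sprintf("%s\t%d\t%d\t%s\t%d", x$chrom, as.integer(x$start),
            as.integer(x$end), x$cell_id, as.integer(x$copy_number))
  } else character(0)
  writeLines(c(header, lines), path)
  invisible(path)
}

# read a headerless TSV body (after `skip` lines), tolerating empty files
read_tsv_body <- function(path, col_names, col_types, skip = 0) {
  n_data <- length(readLines(path)) - skip
  if (n_data <= 0) {
    proto <- purrr::map(strsplit(col_types, "")[[1]], function(tc)
      switch(tc, c = character(0), i = integer(0), n = numeric(0)))
    return(as_tibble(stats::setNames(proto, col_names)))
  }
  readr::read_tsv(path, comment = "", skip = skip, show_col_types = FALSE,
                  col_names = col_names, col_types = col_types)
}

#' @rdname ctcna_io
#' @export
read_truth <- function(path) {
  df <- read_tsv_body(
    path, c("chrom", "start", "end", "cell_id", "copy_number"), "cnnci",
    skip = 1
  )
  df[, c("cell_id", "chrom", "start", "end", "copy_number")] |> as_tibble()
}

#' @rdname ctcna_io
#' @export
export_calls <- function(x, path) {
  calls <- if (inherits(x, "cna_calls")) x$calls else x
  header <- "#chrom\tstart\tend\tcell_id\tcopy_number\tp_mw\tp_ks"
  lines <- if (nrow(calls) > 0) {
    sprintf("%s\t%d\t%d\t%s\t%d\t%.6g\t%.6g", calls$chrom,
            as.integer(calls$start), as.integer(calls$end), calls$cell_id,
            as.integer(calls$copy_number), calls$p_mw, calls$p_ks)
  } else character(0)
  writeLines(c(header, lines), path)
  invisible(path)
}

#' @rdname ctcna_io
#' @export
read_calls <- function(path) {
  df <- read_tsv_body(
    path,
    c("chrom", "start", "end", "cell_id", "copy_number", "p_mw", "p_ks"),
    "cnncinn", skip = 1
  )
  df[, c("cell_id", "chrom", "start", "end", "copy_number", "p_mw", "p_ks")] |>
    as_tibble()
}

#' Load a focal-region list
#'
#' Reads a BED-like table of disease-relevant focal regions: columns
#' `chrom`, `start`, `end`, `label` (cytogenetic-band style identifier),
#' `kind` (`"amplification"` or `"deletion"`) and `genes` (comma-joined gene
#' identifiers, may be empty).
#'
#' @param path Path to the region file (TSV, `#` comments allowed).
#' @return Tibble of validated regions with a list-column `genes`.
#' @export
load_region_list <- function(path) {
  body <- readLines(path)
  skip <- sum(startsWith(body, "#"))
  df <- read_tsv_body(
    path, c("chrom", "start", "end", "label", "kind", "genes"), "cnnccc",
    skip = skip
  )
  if (nrow(df) == 0) {
    warn("region list is empty")
    return(mutate(df, genes = list()))
  }
  if (any(is.na(df$start) | is.na(df$end) | df$end <= df$start)) {
    stop_ctcna("malformed region coordinates (need end > start)")
  }
  bad_kind <- setdiff(unique(df$kind), c("amplification", "deletion"))
  if (length(bad_kind) > 0) {
    stop_ctcna("unknown region kind: ", paste(bad_kind, collapse = ", "))
  }
  dup <- unique(df$label[duplicated(df$label)])
  if (length(dup) > 0) {
    stop_ctcna("duplicate region label(s): ", paste(dup, collapse = ", "))
  }
  df$genes <- purrr::map(df$genes, function(g) {
    if (is.na(g) || g == "") character(0) else strsplit(g, ",")[[1]]
  })
  as_tibble(df)
}

#' @rdname load_region_list
#' @param x Region tibble to write.
#' @export
write_region_list <- function(x, path) {
  out <- x
  out$genes <- purrr::map_chr(x$genes, paste, collapse = ",")
  writeLines(
    c("#chrom\tstart\tend\tlabel\tkind\tgenes",
      sprintf("%s\t%d\t%d\t%s\t%s\t%s", out$chrom, as.integer(out$start),
              as.integer(out$end), out$label, out$kind, out$genes)),
    path
  )
  invisible(path)
}

#' Load a gene annotation (BED4)
#'
#' @param path TSV with columns `chrom`, `start`, `end`, `gene`.
#' @return Tibble with columns `gene`, `chrom`, `start`, `end`; entries with
#'   missing coordinates are dropped with a warning.
#' @export
load_gene_annotation <- function(path) {
  skip <- sum(startsWith(readLines(path), "#"))
  df <- read_tsv_body(path, c("chrom", "start", "end", "gene"), "cnnc",
                      skip = skip)
  bad <- is.na(df$start) | is.na(df$end) | is.na(df$chrom)
  if (any(bad)) {
    warn(paste0("dropping ", sum(bad), " gene(s) with missing coordinates"))
    df <- df[!bad, ]
  }
  if (anyDuplicated(df$gene)) {
    stop_ctcna("duplicate gene identifiers in annotation")
  }
  as_tibble(df[, c("gene", "chrom", "start", "end")])
}

#' @rdname load_gene_annotation
#' @param x Gene annotation tibble to write.
#' @export
write_gene_annotation <- function(x, path) {
  writeLines(
    c("#chrom\tstart\tend\tgene",
      sprintf("%s\t%d\t%d\t%s", x$chrom, as.integer(x$start),
              as.integer(x$end), x$gene)),
    path
  )
  invisible(path)
}

#' Read and write gene-set collections (GMT)
#'
#' GMT is tab-separated: term id, description, then one gene per field.
#'
#' @param path GMT file path.
#' @return `read_gmt()`: tibble with columns `term_id`, `term_name` and a
#'   list-column `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  tibble(
    term_id = purrr::map_chr(parts, 1),
    term_name = purrr::map_chr(parts, 2),
    genes = purrr::map(parts, ~ unique(.x[-(1:2)]))
  )
}

#' @rdname read_gmt
#' @param x Gene-set tibble to write.
#' @export
write_gmt <- function(x, path) {
  writeLines(
    purrr::pmap_chr(x, function(term_id, term_name, genes, ...) {
      paste(c(term_id, term_name, genes), collapse = "\t")
    }),
    path
  )
  invisible(path)
}
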