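#' Configure the end-to-end pipeline
#'
#' Validates every stage's parameters before anything runs.
#'
#' @param cohort A [cohort_spec()].
#' @param genome Genome specification (default [toy_genome()]).
#' @param bin_size Bin size in bp.
#' @param penalty,min_bins,alpha CNA-calling parameters.
#' @param direction_mode,aggregate,n_refs Imbalance parameters.
#' @param regions_file,genes_file,gmt_file Paths to the focal-region list,
#'   gene annotation and gene-set collection; defaults are the synthetic
#'   resources shipped with the package.
#' @param edge_threshold Strict shared-gene bound for network edges.
#' @param out_dir Output directory.
#' @param seed Integer seed driving every random draw.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            genome = toy_genome(),
                            bin_size = 1e5,
                            penalty = "auto", min_bins = 5, alpha = 0.05,
                            direction_mode = "status", aggregate = "mean",
                            n_refs = 5,
                            regions_file = ctcna_extdata("focal_regions_synthetic.bed"),
                            genes_file = ctcna_extdata("genes_synthetic.bed"),
                            gmt_file = ctcna_extdata("gene_sets_synthetic.gmt"),
                            edge_threshold = 10,
                            out_dir = tempfile("ctcna_"),
                            seed = 1L) {
  stopifnot(inherits(cohort, "cohort_spec"))
  if (bin_size <= 0) stop_ctcna("calling stage: bin_size must be > 0")
  if (min_bins < 2) stop_ctcna("calling stage: min_bins must be >= 2")
  if (alpha <= 0 || alpha >= 1) stop_ctcna("calling stage: alpha in (0,1)")
  if (!file.exists(regions_file)) {
    stop_ctcna("recurrence stage: region list not found: ", regions_file)
  }
  if (!file.exists(genes_file)) {
    stop_ctcna("enrichment stage: gene annotation not found: ", genes_file)
  }
  if (!file.exists(gmt_file)) {
    stop_ctcna("enrichment stage: gene-set (GMT) file not found: ", gmt_file)
  }
  structure(
    list(cohort = cohort, genome = genome, bin_size = bin_size,
         penalty = penalty, min_bins = min_bins, alpha = alpha,
         direction_mode = direction_mode, aggregate = aggregate,
         n_refs = n_refs, regions_file = regions_file,
         genes_file = genes_file, gmt_file = gmt_file,
         edge_threshold = edge_threshold, out_dir = out_dir,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

ctcna_extdata <- function(file) {
  system.file("extdata", file, package = "ctcna") %||% ""
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors [pipeline_config()] field-for-field; the `cohort` block
#' mirrors [cohort_spec()] (its `patients` entry, if present, is a list of
#' row records).
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort_args <- y$cohort %||% list()
  if (!is.null(cohort_args$patients)) {
    cohort_args$patients <- purrr::map(cohort_args$patients, as_tibble) |>
      purrr::list_rbind()
  }
  for (f in c("aberrant_fraction", "timepoint_effect", "cn_weights")) {
    if (!is.null(cohort_args[[f]])) {
      cohort_args[[f]] <- unlist(cohort_args[[f]])
    }
  }
  cohort <- do.call(cohort_spec, cohort_args)
  args <- y[setdiff(names(y), "cohort")]
  if (!is.null(args$genome)) {
    args$genome <- genome_spec(purrr::map_chr(args$genome, "chrom"),
                               purrr::map_dbl(args$genome, "length"))
  }
  do.call(pipeline_config, c(list(cohort = cohort), args))
}

#' Run the full pipeline
#'
#' simulate -> call CNAs -> Jaccard imbalance + group statistics ->
#' focal-region and gene recurrence -> enrichment -> term network, writing
#' every stage's output under `config$out_dir` and a `manifest.json`
#' recording the seed, the parameters and an md5 hash of every produced
#' file. The same configuration always reproduces identical hashes.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, the manifest (named list).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[ctcna] ", ...)
  files <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_ctcna("pipeline stage '", name, "' failed: ", conditionMessage(e))
    })
  }

  grid <- build_bin_grid(config$genome, config$bin_size)

  say("simulate: ", nrow(config$cohort$patients), " patients")
  cohort <- stage("simulate", simulate_cohort(config$cohort, grid,
                                              seed = config$seed))
  write_counts(cohort$counts, file.path(out, "counts.tsv"))
  write_metadata(cohort$metadata, file.path(out, "metadata.tsv"))
  export_truth(cohort$truth, file.path(out, "truth.bed"))
  files <- c(files, "counts.tsv", "metadata.tsv", "truth.bed")

  say("call-cna: ", nrow(cohort$metadata), " cells")
  calls <- stage("calling", call_cnas(cohort$counts, grid,
                                      penalty = config$penalty,
                                      min_bins = config$min_bins,
                                      alpha = config$alpha))
  export_calls(calls, file.path(out, "calls.bed"))
  readr::write_tsv(calls$cells, file.path(out, "cell_summary.tsv"))
  files <- c(files, "calls.bed", "cell_summary.tsv")

  say("jaccard: scoring CTCs against ", config$n_refs, " leukocytes")
  ji <- stage("jaccard", ji_table(calls, cohort$metadata, grid,
                                  n_refs = config$n_refs,
                                  aggregate = config$aggregate,
                                  direction_mode = config$direction_mode))
  ji_flat <- ji |>
    mutate(per_reference = purrr::map_chr(
      .data$per_reference, ~ paste(signif(.x$ji, 6), collapse = ",")
    ))
  readr::write_tsv(ji_flat, file.path(out, "ji.tsv"))
  files <- c(files, "ji.tsv")

  say("compare-groups")
  comparisons <- stage("compare", purrr::map(
    stats::setNames(nm = c("time_point", "outcome", "time_point_outcome")),
    function(by) {
      cmp <- compare_groups(ji, grouping = by)
      list(groups = cmp$groups, kw_p = cmp$kw_p, pairwise = cmp$pairwise)
    }
  ))
  jsonlite::write_json(comparisons, file.path(out, "comparisons.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  files <- c(files, "comparisons.json")

  say("recurrence")
  regions <- stage("recurrence", load_region_list(config$regions_file))
  annotation <- stage("enrichment", load_gene_annotation(config$genes_file))
  rec <- stage("recurrence",
               region_recurrence(calls, regions, cohort$metadata)) |>
    stratified_percentages()
  gene_rec <- stage("recurrence",
                    gene_recurrence(calls, annotation, cohort$metadata)) |>
    stratified_percentages()
  readr::write_tsv(rec, file.path(out, "recurrence.tsv"))
  readr::write_tsv(gene_rec, file.path(out, "gene_recurrence.tsv"))
  files <- c(files, "recurrence.tsv", "gene_recurrence.tsv")

  say("enrich + network")
  collection <- stage("enrichment", read_gmt(config$gmt_file))
  ctc_ids <- cohort$metadata$cell_id[cohort$metadata$cell_class == "CTC"]
  enr <- stage("enrichment",
               enrich_cells(calls, annotation, collection,
                            alpha = config$alpha, cell_ids = ctc_ids))
  enr_flat <- enr |>
    mutate(overlap_genes = purrr::map_chr(.data$overlap_genes, paste,
                                          collapse = ","))
  readr::write_tsv(enr_flat, file.path(out, "enrichment.tsv"))
  network <- stage("network",
                   build_term_network(enr, cohort$metadata,
                                      edge_threshold = config$edge_threshold))
  export_network(network, graphml = file.path(out, "network.graphml"),
                 nodes_tsv = file.path(out, "nodes.tsv"),
                 edges_tsv = file.path(out, "edges.tsv"))
  files <- c(files, "enrichment.tsv", "network.graphml", "nodes.tsv",
             "edges.tsv")

  manifest <- list(
    seed = config$seed,
    parameters = list(
      bin_size = config$bin_size, penalty = config$penalty,
      min_bins = config$min_bins, alpha = config$alpha,
      direction_mode = config$direction_mode, aggregate = config$aggregate,
      n_refs = config$n_refs, edge_threshold = config$edge_threshold
    ),
    files = as.list(tools::md5sum(file.path(out, files)) |>
                      stats::setNames(files))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("done: ", length(files), " files in ", out)
  invisible(manifest)
}
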