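meta3 <- tibble::tibble(
  cell_id = c("c1", "c2", "c3"),
  patient_id = "P1",
  time_point = c("A", "B", "B"),
  outcome = c("relapsed", "relapsed", "disease_free"),
  cell_class = "CTC",
  phenotype = NA_character_
)

region_amp <- tibble::tibble(chrom = "chr1", start = 5e6, end = 8e6,
                             label = "1q21_amp", kind = "amplification",
                             genes = list("G1"))

test_that("the shipped focal-region list loads with 23 + 19 entries", {
  path <- system.file("extdata", "focal_regions_synthetic.bed",
                      package = "ctcna")
  regions <- load_region_list(path)
  expect_equal(sum(regions$kind == "amplification"), 23)
  expect_equal(sum(regions$kind == "deletion"), 19)
  expect_equal(nrow(regions), 42)
  expect_false(anyDuplicated(regions$label) > 0)
})

test_that("malformed region lists are rejected, empty ones warned about", {
  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t50\tr1\tamplification\tG1", bad)
  expect_error(load_region_list(bad), "coordinates")

  writeLines("chr1\t0\t100\tr1\tweird\tG1", bad)
  expect_error(load_region_list(bad), "weird")

  writeLines(c("chr1\t0\t100\tr1\tamplification\tG1",
               "chr2\t0\t100\tr1\tdeletion\tG2"), bad)
  expect_error(load_region_list(bad), "r1")

  writeLines(character(0), bad)
  expect_warning(out <- load_region_list(bad), "empty")
  expect_equal(nrow(out), 0)
})

test_that("a cell counts once per region, direction gated by match_kind", {
  calls <- tibble::tibble(
    cell_id = c("c1", "c1", "c2"),
    chrom = "chr1",
    start = c(5.5e6, 6.5e6, 5e6),
    end = c(6e6, 7e6, 7e6),
    copy_number = c(3L, 4L, 1L)
  )
  rec <- region_recurrence(calls, region_amp, meta3, match_kind = TRUE)
  # c1 has two gains inside the amplification region but counts once;
  # c2's loss does not match the region kind
  tp <- rec[rec$stratum_type == "time_point", ]
  expect_equal(sum(tp$count), 1)
  expect_equal(tp$count[tp$stratum == "A"], 1)

  rec_any <- region_recurrence(calls, region_amp, meta3, match_kind = FALSE)
  expect_equal(sum(rec_any$count[rec_any$stratum_type == "outcome"]), 2)
})

test_that("time-point counts sum to the all-cell count of a region", {
  withr::local_seed(7)
  calls <- purrr::map(1:12, function(i) {
    tibble::tibble(cell_id = paste0("c", i), chrom = "chr1",
                   start = runif(1, 0, 9e6), end = NA_real_,
                   copy_number = sample(c(1L, 3L), 1))
  }) |> purrr::list_rbind() |>
    dplyr::mutate(end = start + 2e6)
  meta <- tibble::tibble(
    cell_id = paste0("c", 1:12), patient_id = "P1",
    time_point = rep(c("A", "B", "C"), 4),
    outcome = rep(c("relapsed", "disease_free"), 6),
    cell_class = "CTC", phenotype = NA_character_
  )
  rec <- region_recurrence(calls, region_amp, meta, match_kind = FALSE)
  tp <- rec[rec$stratum_type == "time_point", ]
  carriers <- length(unique(calls$cell_id[
    pmin(calls$end, 8e6) - pmax(calls$start, 5e6) >= 1
  ]))
  expect_equal(sum(tp$count), carriers)
  expect_true(all(rec$count <= rec$total))
})

test_that("gene recurrence counts cells overlapping each gene", {
  genes <- tibble::tibble(gene = c("G1", "G2"), chrom = "chr1",
                          start = c(5.6e6, 9e6), end = c(5.9e6, 9.5e6))
  calls <- tibble::tibble(cell_id = "c1", chrom = "chr1", start = 5e6,
                          end = 8e6, copy_number = 3L)
  rec <- gene_recurrence(calls, genes, meta3)
  out <- rec[rec$stratum_type == "outcome", ]
  expect_equal(sum(out$count[out$label == "G1"]), 1)
  expect_equal(sum(out$count[out$label == "G2"]), 0)

  # a whole-chromosome call hits every gene on it
  whole <- tibble::tibble(cell_id = "c1", chrom = "chr1", start = 0,
                          end = 10e6, copy_number = 3L)
  rec2 <- gene_recurrence(whole, genes, meta3)
  expect_true(all(tapply(rec2$count, rec2$label, sum) > 0))
})

test_that("percentages divide counts by stratum totals at one decimal", {
  m <- tibble::tibble(
    label = "G", kind = "gene",
    stratum_type = "outcome",
    stratum = c("relapsed", "disease_free", "empty"),
    count = c(8L, 3L, 0L),
    total = c(29L, 28L, 0L)
  )
  out <- stratified_percentages(m)
  expect_equal(out$percent, c(27.6, 10.7, NA_real_))
})
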