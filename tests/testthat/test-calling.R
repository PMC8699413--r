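test_that("median normalization maps constant counts to ratio 1", {
  grid <- tiny_grid(200)
  prof <- normalize_counts(rep(100L, 200), grid)
  expect_true(all(prof$ratio == 1))

  counts <- rep(100L, 200)
  counts[51:100] <- 200L
  prof2 <- normalize_counts(counts, grid)
  expect_equal(unique(prof2$ratio[1:50]), 1)
  expect_equal(unique(prof2$ratio[51:100]), 2)

  expect_error(normalize_counts(rep(0L, 200), grid), "no signal")
  expect_error(normalize_counts(rep(1L, 10), grid), "does not match")
})

test_that("segmentation finds a single step where the exhaustive scan does", {
  withr::local_seed(101)
  # multiplicative noise, as read counts produce on the ratio scale
  ratio <- 2^(rep(log2(c(1, 2)), c(1000, 500)) + rnorm(1500, 0, 0.05))
  prof <- make_profile(ratio)
  segs <- segment_profile(prof, min_bins = 5)
  expect_equal(nrow(segs), 2)
  k_oracle <- oracle_one_changepoint(log2(ratio + 1e-6), min_len = 5)
  expect_lte(abs((segs$start_bin[2] + 1) - k_oracle), 3)
  expect_lte(abs(segs$start_bin[2] - 1000), 3)
})

test_that("a constant profile yields one segment per chromosome", {
  grid <- build_bin_grid(genome_spec(c("chr1", "chr2"), c(5e6, 3e6)), 1e5)
  prof <- normalize_counts(rep(80L, nrow(grid)), grid)
  segs <- segment_profile(prof)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$chrom, c("chr1", "chr2"))
})

test_that("a two-sided step is split where the exhaustive 2-point scan says", {
  withr::local_seed(102)
  ratio <- 2^(rep(log2(c(1, 0.5, 1)), c(100, 60, 100)) + rnorm(260, 0, 0.05))
  prof <- make_profile(ratio)
  segs <- segment_profile(prof, min_bins = 5)
  expect_equal(nrow(segs), 3)
  kl <- oracle_two_changepoints(log2(ratio + 1e-6), min_len = 5)
  expect_lte(abs((segs$start_bin[2] + 1) - kl[1]), 3)
  expect_lte(abs((segs$start_bin[3] + 1) - kl[2]), 3)
})

test_that("segments tile the valid bins and respect min_bins", {
  withr::local_seed(103)
  for (rep in 1:5) {
    ratio <- 2^(rep(sample(c(0, 0.6, -0.8), 3), each = 100) +
                  rnorm(300, 0, 0.1))
    segs <- segment_profile(make_profile(ratio), min_bins = 5)
    expect_true(all(segs$n_bins >= 5))
    expect_equal(sort(unlist(segs$bins)), 0:299)
  }
})

test_that("copy-number assignment rounds half away from zero", {
  expect_equal(assign_copy_number(1.52), 3L)
  expect_equal(assign_copy_number(0.02), 0L)
  expect_equal(assign_copy_number(1.25), 3L) # 2.5 rounds up
  expect_equal(assign_copy_number(0.75), 2L) # 1.5 rounds to 2, not 1
  expect_equal(assign_copy_number(-0.2), 0L) # floored at 0
})

test_that("dual-test p-values match exact enumeration on small samples", {
  p <- score_segment_significance(c(1, 2, 3), c(4, 5, 6))
  expect_equal(p$p_mw, 0.1) # U = 0, 2/20 arrangements as extreme

  p2 <- score_segment_significance(c(1, 2), c(3, 4))
  d <- suppressWarnings(stats::ks.test(c(1, 2), c(3, 4))$statistic)
  expect_equal(unname(d), 1) # disjoint supports

  p3 <- score_segment_significance(c(1, 2, 3), c(1, 2, 3))
  expect_equal(p3$p_mw, 1) # identical samples, exact enumeration with ties

  expect_error(score_segment_significance(numeric(0), 1), "non-empty")
})

test_that("only segments passing both tests at alpha are called", {
  withr::local_seed(104)
  grid <- tiny_grid(300)
  ratio <- c(rnorm(150, 1, 0.05), rnorm(60, 2, 0.05), rnorm(90, 1, 0.05))
  prof <- make_profile(ratio)
  segs <- segment_profile(prof)
  cc <- call_significant_cnas(prof, segs, grid)
  expect_equal(nrow(cc$calls), 1)
  expect_equal(cc$calls$copy_number, 4L)
  expect_true(all(cc$calls$p_mw < 0.05 & cc$calls$p_ks < 0.05))

  # with alpha tightened to exclude everything, no calls survive
  cc0 <- call_significant_cnas(prof, segs, grid, alpha = 1e-300)
  expect_equal(nrow(cc0$calls), 0)
})

test_that("relaxing the alpha threshold never loses calls", {
  withr::local_seed(105)
  grid <- tiny_grid(400)
  truth <- tibble::tibble(chrom = "chr1", start = c(5e6, 25e6),
                          end = c(12e6, 31e6), copy_number = c(3L, 1L))
  counts <- simulate_cell_counts(grid, truth, 100, 0.05, 0.02, seed = 9)
  prof <- normalize_counts(counts, grid)
  segs <- segment_profile(prof)
  n_calls <- vapply(c(0.001, 0.01, 0.05, 0.2), function(a)
    nrow(call_significant_cnas(prof, segs, grid, alpha = a)$calls),
    integer(1))
  expect_true(all(diff(n_calls) >= 0))
})

test_that("a diploid cell yields no calls in at least 95% of seeded runs", {
  grid <- build_bin_grid(toy_genome(), 1e5)
  n_calls <- vapply(1:100, function(s) {
    counts <- simulate_cell_counts(grid, NULL, 100, 0.05, 0.02, seed = s)
    prof <- normalize_counts(counts, grid)
    nrow(call_significant_cnas(prof, segment_profile(prof), grid)$calls)
  }, integer(1))
  expect_gte(mean(n_calls == 0), 0.95)
})

test_that("a 500-bin CN=4 event is recovered with tight breakpoints", {
  grid <- build_bin_grid(genome_spec("chr1", 200e6), 1e5) # 2000 bins
  truth <- tibble::tibble(chrom = "chr1", start = 50e6, end = 100e6,
                          copy_number = 4L)
  counts <- simulate_cell_counts(grid, truth, 100, 0.05, 0, seed = 21)
  prof <- normalize_counts(counts, grid)
  cc <- call_significant_cnas(prof, segment_profile(prof), grid)
  expect_equal(nrow(cc$calls), 1)
  expect_equal(cc$calls$copy_number, 4L)
  expect_lte(abs(cc$calls$start - 50e6), 3e5) # within 3 bins
  expect_lte(abs(cc$calls$end - 100e6), 3e5)
  expect_equal(cc$aberrant_fraction, cc$calls$n_bins / 2000)
})

test_that("wholly aberrant profiles fall back to a unit reference, flagged", {
  withr::local_seed(106)
  grid <- tiny_grid(60)
  prof <- make_profile(rnorm(60, 2, 0.05))
  segs <- segment_profile(prof)
  cc <- call_significant_cnas(prof, segs, grid)
  expect_true(cc$neutral_fallback)
  expect_equal(nrow(cc$calls), 1)
})

test_that("calls BED round-trips with p-value columns", {
  path <- withr::local_tempfile(fileext = ".bed")
  calls <- tibble::tibble(cell_id = "c1", chrom = "chr2", start = 1e6,
                          end = 2e6, copy_number = 3L, p_mw = 0.001,
                          p_ks = 0.002)
  export_calls(calls, path)
  lines <- readLines(path)
  expect_length(strsplit(lines[2], "\t")[[1]], 7)
  back <- read_calls(path)
  expect_equal(back[, c("cell_id", "chrom", "start", "end", "copy_number")],
               calls[, c("cell_id", "chrom", "start", "end", "copy_number")])
  expect_equal(back$p_mw, 0.001)

  export_calls(calls[0, ], path)
  expect_equal(nrow(read_calls(path)), 0)
})

test_that("cohort-level calling returns per-cell summaries and tidy output", {
  grid <- build_bin_grid(toy_genome(), 1e6)
  patients <- tibble::tibble(patient_id = "P1", outcome = "relapsed",
                             n_A = 2L, n_B = 0L, n_C = 0L)
  co <- simulate_cohort(cohort_spec(patients = patients), grid, seed = 2)
  calls <- call_cnas(co$counts, grid)
  expect_s3_class(calls, "cna_calls")
  expect_equal(nrow(calls$cells), 2 + 5)
  expect_true(all(tidy(calls)$p_mw < 0.05))
  expect_equal(glance(calls)$n_cells, 7)
  track <- copy_number_track(calls, grid,
                             cell_ids = calls$cells$cell_id[1])
  expect_equal(nrow(track), nrow(grid))
})
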