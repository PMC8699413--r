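test_that("aberrant bin sets follow the call intervals and directions", {
  grid <- tiny_grid(100)
  calls <- tibble::tibble(chrom = "chr1", start = 1e6, end = 2e6,
                          copy_number = 4L)
  s <- aberrant_bin_set(calls, grid)
  expect_equal(s$bin, 10:19)
  expect_true(all(s$direction == "gain"))

  expect_equal(nrow(aberrant_bin_set(calls[0, ], grid)), 0)

  two <- tibble::tibble(chrom = "chr1", start = c(0, 5e6), end = c(1e6, 6e6),
                        copy_number = c(3L, 1L))
  s2 <- aberrant_bin_set(two, grid)
  expect_equal(sum(s2$direction == "gain"), 10)
  expect_equal(sum(s2$direction == "loss"), 10)
  expect_equal(nrow(s2), 20)
})

test_that("Jaccard index counts shared and total aberrant bins", {
  a <- bin_set(1:10)
  b <- bin_set(6:15)
  expect_equal(jaccard_index(a, b), 5 / 15)
  expect_equal(jaccard_index(a, a), 1)
  expect_equal(jaccard_index(a, bin_set(20:25)), 0)
  # both empty: identical fully diploid content
  expect_equal(jaccard_index(bin_set(integer(0)), bin_set(integer(0))), 1)
  # direction only matters in signed mode
  gains <- bin_set(1:10, "gain")
  losses <- bin_set(1:10, "loss")
  expect_equal(jaccard_index(gains, losses, "signed"), 0)
  expect_equal(jaccard_index(gains, losses, "status"), 1)
})

test_that("Jaccard index is symmetric, bounded, and drops when sets diverge", {
  withr::local_seed(42)
  for (i in 1:1000) {
    a <- bin_set(sample(0:99, sample(0:30, 1)))
    b <- bin_set(sample(0:99, sample(0:30, 1)))
    ji <- jaccard_index(a, b)
    expect_identical(ji, jaccard_index(b, a))
    expect_gte(ji, 0)
    expect_lte(ji, 1)
  }
  # adding a bin found in neither set to one set strictly decreases JI
  a <- bin_set(1:10)
  b <- bin_set(5:14)
  expect_lt(jaccard_index(bin_set(c(1:10, 50)), b), jaccard_index(a, b))
})

test_that("per-reference JIs aggregate as configured", {
  cell <- bin_set(1:10)
  refs <- list(r1 = bin_set(1:10), r2 = bin_set(1:10))
  out <- ji_against_references(cell, refs)
  expect_equal(attr(out, "summary_ji"), 1)

  # mean of hand-computed per-reference values
  refs2 <- list(a = bin_set(1:2), b = bin_set(1:2), c = bin_set(1:2),
                d = bin_set(c(1:5, 11:12)), e = bin_set(20:24))
  cell2 <- bin_set(1:5)
  out2 <- ji_against_references(cell2, refs2)
  expect_equal(out2$ji, c(2 / 5, 2 / 5, 2 / 5, 5 / 7, 0))
  expect_equal(attr(out2, "summary_ji"), mean(c(0.4, 0.4, 0.4, 5 / 7, 0)))

  all_mode <- ji_against_references(cell2, refs2, aggregate = "all")
  expect_null(attr(all_mode, "summary_ji"))
  expect_equal(nrow(all_mode), 5)

  expect_error(ji_against_references(cell, list()), "non-empty")
})

test_that("group comparison reproduces the exact rank-sum p and medians", {
  ji <- tibble::tibble(
    summary_ji = c(1, 2, 3, 4, 5, 6),
    time_point = rep(c("A", "B"), each = 3),
    outcome = "relapsed"
  )
  cmp <- compare_groups(ji, "time_point")
  expect_equal(cmp$pairwise$mw_p, 0.1)
  expect_true(is.na(cmp$kw_p)) # only two groups
  expect_equal(cmp$groups$median, c(2, 5))
  expect_equal(tidy(cmp)$mw_p, 0.1)
  expect_equal(glance(cmp)$n_cells, 6)
})

test_that("Kruskal-Wallis type-I error is calibrated under the null", {
  withr::local_seed(77)
  reject <- vapply(1:2000, function(i) {
    x <- rnorm(30)
    g <- rep(c("A", "B", "C"), each = 10)
    stats::kruskal.test(x, factor(g))$p.value < 0.05
  }, logical(1))
  expect_gte(mean(reject), 0.03)
  expect_lte(mean(reject), 0.07)
})

test_that("summary JI decreases monotonically with true aberrant fraction", {
  grid <- build_bin_grid(toy_genome(), 2e5)
  spec <- cohort_spec()
  n_bins <- nrow(grid)
  # shared WGA-bias loci, as in the cohort generator
  bias <- rep(1, n_bins)
  bias[c(101:112, 501:512, 901:912)] <- spec$artifact_multiplier
  sim_cell <- function(frac, seed) {
    truth <- if (frac == 0) NULL else
      withr::with_seed(seed, sample_truth_cnas(grid, frac, spec))
    counts <- simulate_cell_counts(grid, truth, 100, 0.05, 0.02,
                                   seed = seed + 1L, bias = bias)
    prof <- normalize_counts(counts, grid)
    cc <- call_significant_cnas(prof, segment_profile(prof), grid)
    list(
      set = aberrant_bin_set(cc$calls, grid),
      realized = if (is.null(truth)) 0 else
        truth_aberrant_fraction(dplyr::mutate(truth, cell_id = "x"),
                                grid)$truth_fraction
    )
  }
  refs <- purrr::map(1:5, ~ sim_cell(0, 9000 + .x)$set)
  names(refs) <- paste0("wbc", 1:5)
  fracs <- seq(0, 0.6, length.out = 50)
  cells <- purrr::map(seq_along(fracs),
                      ~ sim_cell(fracs[.x], 100 + 7 * .x))
  ji <- vapply(cells, function(cl)
    attr(ji_against_references(cl$set, refs), "summary_ji"), numeric(1))
  realized <- vapply(cells, `[[`, numeric(1), "realized")
  rho <- stats::cor(ji, realized, method = "spearman")
  expect_lt(rho, -0.9)
})

test_that("distribution summaries match the comparison medians and plot out", {
  ji <- tibble::tibble(summary_ji = c(0.1, 0.2, 0.3),
                       time_point = "A", outcome = "relapsed")
  out <- summarize_distribution(ji, "time_point")
  expect_equal(out$median, 0.2)

  empty <- summarize_distribution(ji[0, ], "time_point")
  expect_equal(nrow(empty), 0)

  svg <- withr::local_tempfile(fileext = ".svg")
  ji2 <- tibble::tibble(
    summary_ji = runif(57),
    time_point = rep(c("A", "B", "C"), c(20, 27, 10)),
    outcome = "relapsed"
  )
  out2 <- summarize_distribution(ji2, "time_point", plot_file = svg)
  expect_equal(out2$n, c(20L, 27L, 10L))
  expect_true(file.size(svg) > 0)
  cmp <- compare_groups(ji2, "time_point")
  expect_equal(sort(out2$median), sort(cmp$groups$median))
})
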