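ann4 <- tibble::tibble(
  gene = c("g1", "g2", "g3", "g4"),
  chrom = "chr1",
  start = c(0.1e6, 0.9e6, 2e6, 3e6),
  end = c(0.2e6, 1.1e6, 2.1e6, 3.1e6)
)

test_that("gene extraction honors overlap vs containment semantics", {
  call <- tibble::tibble(chrom = "chr1", start = 0, end = 1e6,
                         copy_number = 3L)
  expect_setequal(genes_in_calls(call, ann4, "any_overlap"), c("g1", "g2"))
  expect_equal(genes_in_calls(call, ann4, "contained"), "g1")
  expect_equal(genes_in_calls(call[0, ], ann4), character(0))
  whole <- tibble::tibble(chrom = "chr1", start = 0, end = 10e6,
                          copy_number = 1L)
  expect_setequal(genes_in_calls(whole, ann4), ann4$gene)
})

test_that("hypergeometric p equals the closed form and handles edges", {
  universe <- paste0("u", 1:10)
  coll <- tibble::tibble(term_id = "T1", term_name = "term one",
                         genes = list(paste0("u", 1:5)))
  res <- hypergeometric_enrich(c("u1", "u2"), coll, universe)
  expect_equal(res$p, choose(5, 2) / choose(10, 2)) # 0.2222...

  # zero overlap: P[X >= 0] = 1
  res0 <- hypergeometric_enrich(c("u6", "u7"), coll["genes"] |>
                                  dplyr::mutate(term_id = "T1",
                                                term_name = "t"), universe)
  expect_equal(res0$p, 1)

  # query = term = universe
  coll_all <- tibble::tibble(term_id = "T", term_name = "t",
                             genes = list(universe))
  expect_equal(hypergeometric_enrich(universe, coll_all, universe)$p, 1)

  expect_warning(out <- hypergeometric_enrich(character(0), coll, universe),
                 "empty")
  expect_equal(nrow(out), 0)
  expect_warning(hypergeometric_enrich(c("u1", "zzz"), coll, universe),
                 "not in universe")
})

test_that("hypergeometric p matches subset enumeration on small universes", {
  withr::local_seed(31)
  for (i in 1:50) {
    n_u <- sample(6:12, 1)
    universe <- paste0("g", seq_len(n_u))
    term <- sample(universe, sample(2:(n_u - 1), 1))
    q_size <- sample(2:min(6, n_u - 1), 1)
    query <- sample(universe, q_size)
    coll <- tibble::tibble(term_id = "T", term_name = "t",
                           genes = list(term))
    p_impl <- hypergeometric_enrich(query, coll, universe)$p
    p_oracle <- oracle_hyper_p(universe, term, q_size,
                               length(intersect(query, term)))
    expect_equal(p_impl, p_oracle, tolerance = 1e-12)
  }
})

test_that("BH adjustment follows the step-up rule and ignores input order", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_equal(bh_adjust(rep(0.2, 4)), rep(0.2, 4))
  withr::local_seed(8)
  for (i in 1:20) {
    p <- runif(sample(3:12, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  }
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("a cell whose aberrant genes form one term retains only that term", {
  withr::local_seed(12)
  universe <- paste0("g", 1:1000)
  term_genes <- paste0("g", 1:30)
  ann <- tibble::tibble(
    gene = universe, chrom = "chr1",
    start = (seq_along(universe) - 1) * 1e5,
    end = (seq_along(universe) - 1) * 1e5 + 5e4
  )
  coll <- tibble::tibble(
    term_id = c("HIT", paste0("BG", 1:10)),
    term_name = c("the aberrant program", paste0("background ", 1:10)),
    genes = c(list(term_genes),
              purrr::map(1:10, ~ sample(paste0("g", 200:1000), 40)))
  )
  call <- tibble::tibble(chrom = "chr1", start = 0, end = 30 * 1e5 - 5e4,
                         copy_number = 4L)
  res <- enrich_cell(call, ann, coll)
  expect_equal(res$term_id, "HIT")
  expect_lt(res$p_adj, 1e-6)
  expect_true(all(res$p_adj <= 0.05))
  expect_true(all(res$p_adj >= res$p))

  expect_equal(nrow(enrich_cell(call[0, ], ann, coll)), 0)
})

test_that("a term hit preferentially in relapsed cells shows the contrast", {
  universe <- paste0("g", 1:400)
  ann <- tibble::tibble(
    gene = universe, chrom = "chr1",
    start = (seq_along(universe) - 1) * 1e5,
    end = (seq_along(universe) - 1) * 1e5 + 5e4
  )
  coll <- withr::with_seed(5, tibble::tibble(
    term_id = c("REG", paste0("BG", 1:5)),
    term_name = c("regulatory program", paste0("background ", 1:5)),
    genes = c(list(paste0("g", 1:30)),
              purrr::map(1:5, ~ sample(paste0("g", 100:400), 30)))
  ))
  reg_span <- c(0, 30 * 1e5 - 5e4) # covers the REG term genes
  for (run in 1:10) {
    withr::local_seed(600 + run)
    cells <- purrr::map(1:20, function(i) {
      outcome <- if (i <= 10) "relapsed" else "disease_free"
      p_hit <- if (outcome == "relapsed") 0.7 else 0.2
      hit <- runif(1) < p_hit
      start <- if (hit) reg_span[1] else 20e6 + runif(1, 0, 10e6)
      tibble::tibble(cell_id = paste0("c", i), outcome = outcome,
                     chrom = "chr1", start = start, end = start + 3e6,
                     copy_number = 3L)
    }) |> purrr::list_rbind()
    pct <- purrr::map_dbl(c("relapsed", "disease_free"), function(oc) {
      ids <- unique(cells$cell_id[cells$outcome == oc])
      enriched <- vapply(ids, function(id) {
        res <- suppressWarnings(
          enrich_cell(cells[cells$cell_id == id, ], ann, coll))
        "REG" %in% res$term_id
      }, logical(1))
      100 * mean(enriched)
    })
    expect_gt(pct[1], pct[2])
  }
})
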