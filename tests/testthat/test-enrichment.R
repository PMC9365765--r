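test_that("hypergeometric upper tail matches exact enumeration", {
  expect_equal(hypergeom_upper(10, 4, 5, 4), 6 / 252)
  expect_equal(hypergeom_upper(20, 5, 5, 5), 1 / choose(20, 5))
  expect_equal(hypergeom_upper(100, 10, 20, 0), 1)
  for (case in list(c(30, 8, 10, 3), c(50, 20, 10, 7), c(12, 6, 6, 4))) {
    expect_equal(hypergeom_upper(case[1], case[2], case[3], case[4]),
                 hyper_oracle(case[1], case[2], case[3], case[4]))
  }
  expect_error(hypergeom_upper(10, 12, 5, 3), "B <= N")
  expect_error(hypergeom_upper(10, 4, 5, 5), "min")
})

test_that("enrichment folds reproduce published reference values within 1%", {
  expect_equal(enrichment_fold(745, 75, 212, 51), 2.38, tolerance = 0.01)
  expect_equal(enrichment_fold(745, 48, 212, 33), 2.41, tolerance = 0.01)
  expect_equal(enrichment_fold(745, 251, 212, 107), 1.49, tolerance = 0.01)
  expect_equal(enrichment_fold(745, 15, 326, 15), 2.3, tolerance = 0.01)
  expect_equal(enrichment_fold(100, 10, 50, 5), 1)
  expect_error(enrichment_fold(100, 0, 50, 0), "B = 0")
})

test_that("fold and p are coherent in b", {
  N <- 80; B <- 20; n <- 25
  folds <- vapply(0:20, function(b) enrichment_fold(N, B, n, b), numeric(1))
  ps <- vapply(0:20, function(b) hypergeom_upper(N, B, n, b), numeric(1))
  expect_true(all(diff(ps) < 0))             # p strictly decreases with b
  expect_equal(folds > 1, (0:20) / n > B / N) # fold > 1 iff target frequency higher
})

test_that("BH q-values match the hand-computed step-up on reference vectors", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.001, 0.5)), c(0.002, 0.5))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("BH equals a brute-force step-up on 1000 random p-vectors", {
  withr::with_seed(123, {
    for (i in 1:1000) {
      p <- runif(sample(1:20, 1))
      expect_identical(bh_fdr(p), bh_oracle(p))
    }
  })
})

test_that("cluster enrichment flags planted signal terms and not noise", {
  truth <- partition_tbl(sprintf("g%03d", 1:200), rep(1:4, each = 50))
  ann <- generate_annotations(truth, n_terms = 24, signal_terms_per_cluster = 2,
                              signal_purity = 0.9, seed = 2)
  target <- truth$gene[truth$community == 1]
  rec <- enrich_cluster(target, truth$gene, ann)
  sig <- rec[rec$significant, ]
  home1 <- ann$term_id[!is.na(ann$home_cluster) & ann$home_cluster == 1]
  expect_true(all(home1 %in% sig$term_id))
  noise_ids <- ann$term_id[is.na(ann$home_cluster)]
  expect_false(any(noise_ids %in% sig$term_id))
  expect_true(all(rec$q >= rec$p))
  expect_true(all(rec$b <= pmin(rec$B, rec$n)))
})

test_that("target equal to background yields fold 1 everywhere and no hits", {
  truth <- partition_tbl(sprintf("g%03d", 1:100), rep(1:2, each = 50))
  ann <- generate_annotations(truth, n_terms = 8, signal_terms_per_cluster = 1,
                              seed = 5)
  rec <- enrich_cluster(truth$gene, truth$gene, ann)
  expect_true(all(rec$fold == 1))
  expect_true(all(rec$p == 1))
  expect_false(any(rec$significant))
  expect_error(enrich_cluster(character(0), truth$gene, ann), "empty")
  expect_error(enrich_cluster("not_there", truth$gene, ann), "subset")
})

test_that("the printed worked example flows through enrich_cluster unchanged", {
  # 745-gene background, 212-gene target, one 75-gene term hitting 51 members
  bg <- sprintf("g%03d", 1:745)
  target <- bg[1:212]
  term <- c(bg[1:51], bg[300:323]) # 51 in target, 24 outside: B = 75
  ann <- tibble::tibble(term_id = "T1", term_name = "chromatin organization",
                        genes = list(term))
  rec <- enrich_cluster(target, bg, ann)
  expect_equal(rec$b, 51)
  expect_equal(rec$B, 75)
  expect_equal(rec$fold, enrichment_fold(745, 75, 212, 51))
  expect_equal(rec$p, hypergeom_upper(745, 75, 212, 51))
})

test_that("cell summaries count unique enriched genes", {
  cells <- list(X = sprintf("g%02d", 1:100), Y = sprintf("g%02d", 1:10))
  recs <- list(
    X = tibble::tibble(
      term_id = c("T1", "T2"), significant = c(TRUE, TRUE),
      q = c(1e-4, 1e-3),
      hit_genes = list(sprintf("g%02d", 1:5), sprintf("g%02d", 3:8))
    ),
    Y = tibble::tibble(term_id = character(), significant = logical(),
                       q = numeric(), hit_genes = list())
  )
  out <- summarize_cells(cells, recs)
  x <- out[out$cell == "X", ]
  expect_equal(x$genes_enriched, 8) # union of overlapping terms, not 11
  expect_equal(x$enriched_ratio, 0.08)
  expect_equal(x$n_terms, 2)
  expect_equal(x$median_neglog_q, median(-log10(c(1e-4, 1e-3))))
  y <- out[out$cell == "Y", ]
  expect_equal(y$n_terms, 0)
  expect_true(is.na(y$median_neglog_q))
  expect_true(all(out$enriched_ratio >= 0 & out$enriched_ratio <= 1))
})

test_that("regrouping control destroys planted enrichment", {
  truth <- partition_tbl(sprintf("g%03d", 1:200), rep(1:4, each = 50))
  ann <- generate_annotations(truth, n_terms = 24, signal_terms_per_cluster = 2,
                              signal_purity = 0.9, seed = 7)
  ctrl <- regroup_control(truth, ann, n_replicates = 10, seed = 7)
  expect_equal(nrow(ctrl$replicates), 10)

  true_terms <- sum(vapply(1:4, function(cl) {
    rec <- enrich_cluster(truth$gene[truth$community == cl], truth$gene, ann)
    sum(rec$significant)
  }, numeric(1)))
  expect_gt(true_terms, ctrl$mean_terms)

  empty_ann <- tibble::tibble(term_id = "T1", term_name = "unrelated",
                              genes = list(sprintf("zz%02d", 1:10)))
  ctrl0 <- regroup_control(truth, empty_ann, n_replicates = 3, seed = 1)
  expect_true(all(ctrl0$replicates$n_terms == 0))
  expect_true(all(ctrl0$replicates$genes_enriched == 0))
})

test_that("term-count concordance reuses the Cramer's V machinery", {
  diag_cells <- tibble::tibble(
    core_cluster = rep(1:3, each = 3), full_cluster = rep(1:3, 3),
    n_terms = as.integer(c(5, 0, 0, 0, 7, 0, 0, 0, 4))
  )
  expect_equal(term_table_v(diag_cells)$v, 1)

  uniform <- dplyr::mutate(diag_cells, n_terms = 3L)
  expect_equal(term_table_v(uniform)$v, 0)

  withr::with_seed(3, {
    rnd <- dplyr::mutate(diag_cells, n_terms = rpois(9, 4) + 1L)
  })
  m <- matrix(rnd$n_terms, 3, byrow = TRUE)
  expect_equal(term_table_v(rnd)$v, cramers_v_oracle(m), tolerance = 1e-12)
})
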