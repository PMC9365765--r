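test_that("lfr_params rejects infeasible configurations", {
  expect_error(lfr_params(100, 10, 50, min_comm = 60, max_comm = 40), "min_comm")
  expect_error(lfr_params(100, 10, 50, min_comm = 40, max_comm = 200), "max_comm")
  expect_error(lfr_params(100, 60, 50, min_comm = 20, max_comm = 40), "avg_degree")
  expect_error(lfr_params(100, 10, 50, mu_w = 0, min_comm = 20, max_comm = 40), "mu_w")
  expect_error(lfr_params(100, 30, 50, min_comm = 25, max_comm = 50), "Infeasible")
})

test_that("the benchmark generator honours its degree and community targets", {
  p <- small_lfr_params(seed = 8)
  pl <- generate_lfr(p)
  expect_setequal(pl$truth$gene, network_genes(pl$network))

  deg <- table(c(pl$network$gene_a, pl$network$gene_b))
  expect_lt(abs(mean(deg) - p$avg_degree) / p$avg_degree, 0.1)
  expect_lte(max(deg), p$max_degree)

  sizes <- community_sizes(pl$truth)$size
  expect_equal(sum(sizes), p$n_nodes)
  expect_true(all(sizes >= p$min_comm - 1))

  expect_true(all(pl$network$weight > 0 & pl$network$weight <= 1))
})

test_that("the realized weighted mixing tracks mu_w", {
  pl <- generate_lfr(small_lfr_params(seed = 9))
  mix <- external_weight_fraction(pl$network, pl$truth)
  expect_lt(abs(mean(mix$external_fraction) - 0.2), 0.05)
  expect_lt(mean(abs(mix$external_fraction - 0.2)), 0.05)
})

test_that("generation is bit-identical for identical parameters and seed", {
  a <- generate_lfr(small_lfr_params(seed = 5))
  b <- generate_lfr(small_lfr_params(seed = 5))
  expect_identical(a$network, b$network)
  expect_identical(a$truth$community, b$truth$community)
  c <- generate_lfr(small_lfr_params(seed = 6))
  expect_false(identical(a$network, c$network))
})

test_that("node selection modes behave as specified", {
  net <- edge_tbl(c("a", "b", "b", "c"), c("b", "c", "d", "d"),
                  c(0.9, 0.9, 0.9, 0.1))
  s <- node_strength(net)
  top2 <- select_nodes(net, "top_strength", 2)
  expect_equal(top2, s$gene[order(-s$strength, s$gene)][1:2])

  all_top <- select_nodes(net, "top_strength", 4)
  all_rand <- select_nodes(net, "distribution_matched", 4, seed = 1)
  expect_setequal(all_top, network_genes(net))
  expect_setequal(all_rand, network_genes(net))
  expect_error(select_nodes(net, "top_strength", 10), "exceeds")

  # deterministic tie-break by node id
  tie <- edge_tbl(c("x", "a"), c("y", "b"), c(0.5, 0.5))
  expect_equal(select_nodes(tie, "top_strength", 2), c("a", "b"))
})

test_that("strength-ranked selection keeps the planted community structure", {
  cal <- suppressMessages(
    benchmark_calibration(small_lfr_params(seed = 3), size = 60,
                          n_replicates = 5, seed = 3, n_restarts = 5)
  )
  expect_gte(cal$v_strong$v, 0.95)
  expect_equal(nrow(cal$v_avg$replicates), 5)
  expect_gt(cal$v_strong$v, cal$v_avg$mean_v)
})

test_that("tissue generator validates the core placement", {
  expect_error(generate_tissue(core_size = 0), "positive")
  expect_error(generate_tissue(n_nodes = 100, core_size = 200), "<=")
  expect_error(generate_tissue(concordance = 1.5), "concordance")
  expect_error(generate_tissue(n_nodes = 100, core_size = 90, hub_fraction = 0.1),
               "capacity")
})

test_that("fully concordant tissues give near-perfect core-full concordance", {
  sim <- generate_tissue(n_nodes = 600, core_size = 60, concordance = 1, seed = 6)
  full <- louvain_communities(sim$network, seed = 6, n_restarts = 3)
  sub <- suppressMessages(core_subgraph(sim$network, sim$core))
  cp <- louvain_communities(sub, seed = 6, n_restarts = 3)
  v1 <- suppressMessages(cramers_v(cluster_contingency(cp, full))$v)
  expect_gte(v1, 0.9)

  sim0 <- generate_tissue(n_nodes = 600, core_size = 60, concordance = 0, seed = 6)
  full0 <- louvain_communities(sim0$network, seed = 6, n_restarts = 3)
  sub0 <- suppressMessages(core_subgraph(sim0$network, sim0$core))
  cp0 <- louvain_communities(sub0, seed = 6, n_restarts = 3)
  v0 <- suppressMessages(cramers_v(cluster_contingency(cp0, full0))$v)
  expect_lt(v0, v1)
})

test_that("synthetic annotations are enriched where they are planted", {
  truth <- partition_tbl(sprintf("g%03d", 1:200), rep(1:4, each = 50))
  ann <- generate_annotations(truth, n_terms = 20, signal_terms_per_cluster = 2,
                              seed = 4)
  expect_equal(nrow(ann), 20)
  expect_true(all(unlist(ann$genes) %in% truth$gene))
  expect_true(all(lengths(ann$genes) > 0))

  signal <- ann[!is.na(ann$home_cluster), ]
  for (i in seq_len(nrow(signal))) {
    home_genes <- truth$gene[truth$community == signal$home_cluster[i]]
    b <- length(intersect(signal$genes[[i]], home_genes))
    fold <- (b / length(signal$genes[[i]])) / (length(home_genes) / nrow(truth))
    expect_gt(fold, 1)
    expect_gte(b / length(signal$genes[[i]]), 0.7)
  }

  noise <- ann[is.na(ann$home_cluster), ]
  frac_c1 <- vapply(noise$genes, function(g) {
    mean(g %in% truth$gene[truth$community == 1])
  }, numeric(1))
  expect_lt(abs(mean(frac_c1) - 0.25), 0.12) # uniform up to sampling error
})

test_that("phenotype generator plants recoverable group effects", {
  cells <- list(CC1 = sprintf("g%03d", 1:100), CC2 = sprintf("g%03d", 101:250),
                CC3 = sprintf("g%03d", 251:400))
  subj <- generate_phenotypes(cells, n_subjects = 3000,
                              iq_shift = c(CC1 = -8), seed = 10)
  expect_equal(nrow(subj), 3000)

  assigned <- assign_subjects(subj, cells$CC1)
  cmp <- welch_compare(assigned, "iq")
  se <- sqrt(sd(subj$iq[assigned$carrier])^2 / cmp$n_in +
               sd(subj$iq[!assigned$carrier])^2 / cmp$n_out)
  expect_lt(abs(cmp$difference - (-8)), 2 * se)

  null_cmp <- welch_compare(assign_subjects(subj, cells$CC3), "iq")
  se0 <- sqrt(sd(subj$iq[assign_subjects(subj, cells$CC3)$carrier])^2 / null_cmp$n_in +
                sd(subj$iq[!assign_subjects(subj, cells$CC3)$carrier])^2 / null_cmp$n_out)
  expect_lt(abs(null_cmp$difference), 2 * se0)

  # subjects without variants always sit in the comparison group
  no_var <- lengths(subj$disruptive_genes) == 0
  expect_true(all(!assigned$carrier[no_var]))
})

test_that("phenotype generation is deterministic under a fixed seed", {
  cells <- list(CC1 = sprintf("g%03d", 1:50))
  a <- generate_phenotypes(cells, n_subjects = 100, seed = 3)
  b <- generate_phenotypes(cells, n_subjects = 100, seed = 3)
  expect_identical(a, b)
  expect_error(generate_phenotypes(cells, n_subjects = 0), "positive")
  expect_error(generate_phenotypes(cells, n_subjects = 10, iq_sd = 0), "positive")
})
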