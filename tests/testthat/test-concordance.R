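test_that("core subgraph keeps only core-core edges and drops isolated cores", {
  net <- edge_tbl(c("A", "B", "C"), c("B", "C", "D"), c(0.5, 0.4, 0.3))
  expect_message(sub <- core_subgraph(net, c("A", "B", "D")), "isolated")
  expect_equal(nrow(sub), 1)
  expect_setequal(network_genes(sub), c("A", "B"))

  expect_identical(core_subgraph(net, c("A", "B", "C", "D")),
                   tibble::as_tibble(net))
  expect_error(core_subgraph(net, c("A", "D")), "no edges")
})

test_that("a planted core list larger than its connected part shrinks accordingly", {
  sim <- generate_tissue(n_nodes = 400, core_size = 50, concordance = 0.5, seed = 3)
  extra <- c(sim$core, sprintf("ghost%02d", 1:5)) # cores absent from the network
  suppressMessages(sub <- core_subgraph(sim$network, extra))
  expect_true(all(network_genes(sub) %in% sim$core))
  expect_lte(length(network_genes(sub)), 50)
})

test_that("contingency tables count joint cluster membership", {
  genes <- sprintf("g%02d", 1:20)
  part <- partition_tbl(genes, rep(1:2, c(12, 8)))
  tab <- cluster_contingency(part, part)
  expect_equal(unname(tab$counts), matrix(c(12L, 0L, 0L, 8L), 2))
  expect_equal(tab$n, 20)

  full4 <- partition_tbl(genes, rep(1:4, 5))
  core4 <- partition_tbl(genes, rep(1:4, each = 5))
  tab16 <- cluster_contingency(core4, full4)
  expect_equal(dim(tab16$counts), c(4, 4))
  expect_equal(length(tab16$counts), 16)
})

test_that("contingency counts match a brute-force double loop on random partitions", {
  genes <- sprintf("g%04d", 1:1000)
  withr::with_seed(11, {
    core <- partition_tbl(genes, sample(1:4, 1000, TRUE))
    full <- partition_tbl(genes, sample(1:5, 1000, TRUE))
  })
  tab <- cluster_contingency(core, full)
  for (i in 1:4) {
    for (j in 1:5) {
      manual <- sum(core$community == i & full$community == j)
      expect_equal(tab$counts[paste0("CC", i), paste0("FC", j)], manual)
    }
  }
})

test_that("unassigned genes are excluded from the contingency table", {
  genes <- sprintf("g%02d", 1:10)
  core <- partition_tbl(genes, rep(1:2, 5))
  full <- partition_tbl(genes, c(rep(1:2, 4), NA, NA))
  expect_message(tab <- cluster_contingency(core, full), "excluded")
  expect_equal(tab$n, 8)
  expect_error(cluster_contingency(core, partition_tbl("zz", 1)), "no assigned genes")
})

test_that("reorder_diagonal maximizes the diagonal against permutation search", {
  expect_equal(unname(reorder_diagonal(matrix(c(0, 8, 12, 0), 2))),
               matrix(c(12, 0, 0, 8), 2))
  diag_tab <- matrix(c(9, 1, 0, 7), 2)
  expect_equal(unname(reorder_diagonal(diag_tab)), diag_tab)

  for (seed in 1:5) {
    m <- withr::with_seed(seed, matrix(rpois(16, 6), 4))
    out <- reorder_diagonal(m)
    # exhaustive search over the 24 column permutations
    perm_list <- list()
    rec <- function(acc, rest) {
      if (length(rest) == 0) {
        perm_list[[length(perm_list) + 1]] <<- acc
      } else {
        for (x in rest) rec(c(acc, x), setdiff(rest, x))
      }
    }
    rec(integer(0), 1:4)
    best <- max(vapply(perm_list, function(p) sum(diag(m[, p])), numeric(1)))
    expect_equal(sum(diag(out)), best)
    expect_equal(sort(as.vector(out)), sort(as.vector(m)))
  }
})

test_that("chi-squared matches hand evaluation of the expected-count formula", {
  expect_equal(chi_squared_stat(matrix(c(5, 5, 5, 5), 2)), 0)
  expect_equal(chi_squared_stat(matrix(c(10, 0, 0, 10), 2)), 20)
  tab <- matrix(c(15, 16, 22, 91), 2)
  expect_equal(chi_squared_stat(tab), chi2_oracle(tab))
  expect_equal(chi_squared_stat(tab), 10.65, tolerance = 1e-3)
  expect_error(suppressWarnings(chi_squared_stat(matrix(0, 2, 2))), "empty")
})

test_that("Cramer's V hits its boundary and reference values", {
  expect_equal(cramers_v(matrix(c(10, 0, 0, 10), 2))$v, 1)
  expect_equal(cramers_v(matrix(c(5, 5, 5, 5), 2))$v, 0)
  res <- cramers_v(matrix(c(15, 16, 22, 91), 2))
  expect_equal(res$v, sqrt((chi2_oracle(matrix(c(15, 16, 22, 91), 2)) / 144) / 1))
  expect_equal(round(res$v, 3), 0.272)
  expect_error(cramers_v(matrix(c(3, 4), 1)), "at least 2")
})

test_that("V is invariant to permutations and transposition, and matches the oracle", {
  for (seed in 1:20) {
    dims <- withr::with_seed(seed, sample(2:6, 2, TRUE))
    m <- withr::with_seed(seed + 100, matrix(rpois(prod(dims), 5) + 1, dims[1]))
    v <- cramers_v(m)$v
    expect_true(v >= 0 && v <= 1)
    expect_equal(v, cramers_v_oracle(m), tolerance = 1e-12)
    perm <- withr::with_seed(seed, list(sample(dims[1]), sample(dims[2])))
    expect_equal(cramers_v(m[perm[[1]], perm[[2]]])$v, v, tolerance = 1e-12)
    expect_equal(cramers_v(t(m))$v, v, tolerance = 1e-12)
  }
})

test_that("empty rows and columns are dropped before X^2 and V", {
  m <- matrix(c(10, 0, 0, 0, 0, 0, 0, 0, 10), 3)
  expect_warning(res <- cramers_v(m), "empty")
  expect_equal(res$k, 2)
  expect_equal(res$r, 2)
  expect_equal(res$v, 1)
})

test_that("sampling control returns the requested replicates and self-concordance is 1", {
  net <- two_cliques()
  full <- louvain_communities(net, seed = 1)
  ctrl <- suppressMessages(
    sample_control(net, size = 8, full_partition = full, n_replicates = 10, seed = 1)
  )
  expect_equal(nrow(ctrl$replicates), 10)
  expect_equal(ctrl$replicates$v, rep(1, 10)) # size = all nodes: full graph back
  expect_true(ctrl$mean_v >= min(ctrl$replicates$v) &&
                ctrl$mean_v <= max(ctrl$replicates$v))
  expect_error(
    sample_control(net, size = 99, full_partition = full),
    "exceeds"
  )
})

test_that("sampling control mean and CI follow the t formula", {
  sim <- generate_tissue(n_nodes = 400, core_size = 40, concordance = 1, seed = 2)
  full <- louvain_communities(sim$network, seed = 2, n_restarts = 3)
  ctrl <- suppressMessages(
    sample_control(sim$network, size = 60, full_partition = full,
                   n_replicates = 5, seed = 2)
  )
  v <- ctrl$replicates$v
  half <- qt(0.975, 4) * sd(v) / sqrt(5)
  expect_equal(ctrl$mean_v, mean(v))
  expect_equal(c(ctrl$ci_lower, ctrl$ci_upper), c(mean(v) - half, mean(v) + half))
})

test_that("higher planted concordance yields higher core-vs-full V in paired seeds", {
  wins <- 0L
  for (seed in 1:10) {
    vs <- vapply(c(1, 0.2), function(conc) {
      sim <- generate_tissue(n_nodes = 600, core_size = 60, concordance = conc,
                             seed = seed)
      full <- louvain_communities(sim$network, seed = seed, n_restarts = 3)
      sub <- suppressMessages(core_subgraph(sim$network, sim$core))
      cp <- louvain_communities(sub, seed = seed, n_restarts = 3)
      suppressMessages(cramers_v(cluster_contingency(cp, full))$v)
    }, numeric(1))
    wins <- wins + (vs[1] > vs[2])
  }
  expect_gte(wins, 9)
})
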