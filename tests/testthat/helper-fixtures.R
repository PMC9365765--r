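# Small fixtures built in code.

edge_tbl <- function(a, b, w) {
  tibble::tibble(gene_a = a, gene_b = b, weight = w)
}

# two unit-weight triangles joined by a weak bridge
two_triangles <- function(bridge_weight = 0.01) {
  edge_tbl(
    c("a", "a", "b", "d", "d", "e", "c"),
    c("b", "c", "c", "e", "f", "f", "d"),
    c(1, 1, 1, 1, 1, 1, bridge_weight)
  )
}

# two disconnected K4 cliques with unit weights
two_cliques <- function() {
  cl <- function(v) {
    pairs <- t(combn(v, 2))
    edge_tbl(pairs[, 1], pairs[, 2], rep(1, nrow(pairs)))
  }
  dplyr::bind_rows(cl(c("a", "b", "c", "d")), cl(c("e", "f", "g", "h")))
}

# random weighted graph on `genes`, guaranteed >= 3 edges
random_net <- function(genes, p = 0.6, seed = 1) {
  withr::with_seed(seed, {
    pairs <- t(combn(genes, 2))
    repeat {
      keep <- runif(nrow(pairs)) < p
      if (sum(keep) >= 3) break
    }
    edge_tbl(pairs[keep, 1], pairs[keep, 2],
             round(runif(sum(keep), 0.1, 1), 3))
  })
}

partition_tbl <- function(gene, community) {
  tibble::tibble(gene = gene, community = as.integer(community))
}

write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

small_lfr_params <- function(seed = 1) {
  lfr_params(n_nodes = 600, avg_degree = 15, max_degree = 60, tau_degree = 2,
             tau_community = 1.5, mu_w = 0.2, min_comm = 120, max_comm = 250,
             seed = seed)
}

tenth_scale_params <- function(seed = 1) {
  lfr_params(n_nodes = 2500, avg_degree = 30, max_degree = 300, tau_degree = 2,
             tau_community = 1.5, mu_w = 0.2, min_comm = 400, max_comm = 800,
             seed = seed)
}
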