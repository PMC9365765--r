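new_partition <- function(gene, community, modularity = NA_real_) {
  out <- tibble(gene = as.character(gene), community = as.integer(community))
  attr(out, "modularity") <- modularity
  class(out) <- c("gene_partition", class(out))
  out
}

#' Modularity of a partition on a weighted network
#'
#' Newman-Girvan weighted modularity at resolution 1:
#' Q = (1/2m) * sum_ij (w_ij - s_i s_j / 2m) delta(c_i, c_j),
#' where m is the total edge weight and s the node strength. Q is 0 for the
#' all-in-one partition and bounded by 1.
#'
#' @param edges A gene network edge tibble.
#' @param partition A tibble with columns `gene` and `community` covering
#'   every gene of the network.
#' @return The modularity Q as a single number.
#' @export
modularity_score <- function(edges, partition) {
  genes <- network_genes(edges)
  comm <- setNames(partition$community, partition$gene)
  missing <- setdiff(genes, partition$gene)
  if (length(missing) > 0) {
    abort(sprintf("Partition does not cover %d network gene(s), e.g. '%s'.",
                  length(missing), missing[1]))
  }
  w <- as.numeric(edges[[3]])
  m <- sum(w)
  if (m <= 0) abort("Network has no edge weight; modularity undefined.")
  same <- comm[as.character(edges[[1]])] == comm[as.character(edges[[2]])]
  w_in <- sum(w[same])
  s <- node_strength(edges)
  s_comm <- rowsum(s$strength, group = comm[s$gene])
  w_in / m - sum((s_comm / (2 * m))^2)
}

#' Seeded Louvain community detection with restarts
#'
#' Greedy modularity maximization (Louvain: local node moves alternating with
#' graph aggregation). The underlying algorithm is randomized; this wrapper
#' runs `n_restarts` independent seeded runs and keeps the partition with the
#' highest modularity, so the result is deterministic given
#' (network, seed, n_restarts). Community ids are re-indexed 1..K by
#' descending community size.
#'
#' @param edges A gene network edge tibble with at least one edge.
#' @param seed Integer seed driving the randomized node orderings.
#' @param n_restarts Number of independent runs to take the best of
#'   (default 10).
#' @param genes Optional vector of genes to include even when isolated in
#'   `edges`; isolated genes become singleton communities.
#' @return A partition tibble (`gene`, `community`) with the achieved
#'   modularity in `attr(, "modularity")`.
#' @export
louvain_communities <- function(edges, seed = 1L, n_restarts = 10L, genes = NULL) {
  if (nrow(edges) == 0) abort("Cannot cluster an edgeless network.")
  verts <- network_genes(edges)
  if (!is.null(genes)) verts <- sort(unique(c(verts, as.character(genes))))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges[[1]]), to = as.character(edges[[2]]),
               weight = as.numeric(edges[[3]])),
    directed = FALSE, vertices = verts
  )
  best <- NULL
  best_q <- -Inf
  for (i in seq_len(n_restarts)) {
    memb <- withr::with_seed(as.integer(seed) + i - 1L, {
      igraph::membership(igraph::cluster_louvain(g, weights = igraph::E(g)$weight))
    })
    part <- tibble(gene = names(memb), community = as.integer(memb))
    q <- modularity_score(edges, part)
    if (q > best_q) {
      best_q <- q
      best <- part
    }
  }
  reindex_by_size(new_partition(best$gene, best$community, best_q))
}

reindex_by_size <- function(partition) {
  q <- attr(partition, "modularity")
  assigned <- partition[!is.na(partition$community), ]
  sizes <- sort(table(assigned$community), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes), names(sizes))
  partition$community <- unname(relabel[as.character(partition$community)])
  partition <- arrange(partition, .data$gene)
  new_partition(partition$gene, partition$community, q)
}

#' Mark communities below a minimum size as unassigned
#'
#' Small communities (fewer than `min_size` members) are excluded from
#' downstream contingency tables: their genes get community `NA`. Retained
#' communities are re-indexed 1..K by descending size.
#'
#' @param partition A partition tibble.
#' @param min_size Minimum community size to retain (default 10 for full
#'   networks; use 1 to keep everything, e.g. for core subgraphs).
#' @return A partition tibble with `NA` communities for unassigned genes.
#' @export
filter_small_communities <- function(partition, min_size = 10L) {
  stopifnot(min_size >= 1)
  sizes <- table(partition$community)
  keep <- names(sizes)[sizes >= min_size]
  if (length(keep) == 0) abort("All communities fall below `min_size`; nothing retained.")
  dropped <- partition$community %in% as.integer(names(sizes)[sizes < min_size])
  if (any(dropped)) {
    inform(sprintf("Marked %d gene(s) in %d small communit(ies) as unassigned.",
                   sum(dropped), sum(sizes < min_size)))
  }
  out <- partition
  out$community[dropped] <- NA_integer_
  reindex_by_size(new_partition(out$gene, out$community))
}

#' Sizes of the communities of a partition
#'
#' @param partition A partition tibble.
#' @return A tibble with columns `community` and `size`, descending by size;
#'   unassigned genes are excluded.
#' @export
community_sizes <- function(partition) {
  partition |>
    filter(!is.na(.data$community)) |>
    count(.data$community, name = "size") |>
    arrange(dplyr::desc(.data$size))
}
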