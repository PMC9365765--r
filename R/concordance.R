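#' Induced subgraph on a core gene set
#'
#' Keeps only the edges whose two endpoints are both core genes. Core genes
#' absent from the network, and core genes left isolated (no core-core edge),
#' are dropped with a message — the core subgraph is a graph of connected core
#' genes only.
#'
#' @param edges A gene network edge tibble.
#' @param core Character vector of core gene identifiers.
#' @return A gene network tibble restricted to core-core edges.
#' @export
core_subgraph <- function(edges, core) {
  core <- unique(as.character(core))
  genes <- network_genes(edges)
  absent <- setdiff(core, genes)
  sub <- edges[edges[[1]] %in% core & edges[[2]] %in% core, ]
  if (nrow(sub) == 0) abort("Core subgraph has no edges.")
  isolated <- setdiff(intersect(core, genes), network_genes(sub))
  if (length(absent) > 0 || length(isolated) > 0) {
    inform(sprintf(
      "Core subgraph: %d core gene(s) absent from the network, %d isolated core gene(s) dropped; %d connected core genes retained.",
      length(absent), length(isolated), length(network_genes(sub))
    ))
  }
  as_tibble(sub)
}

#' Contingency table between core-subgraph and full-network partitions
#'
#' Cell (i, j) counts the genes assigned to core cluster i (rows, labelled
#' CC1..CCr) and full-network cluster j (columns, FC1..FCk). Only genes
#' assigned in both partitions enter; unassigned (NA) genes are excluded with
#' a message. Each non-empty cell is a "subcluster" of the core gene set.
#'
#' @param core_partition Partition of the core subgraph.
#' @param full_partition Partition of the full network.
#' @return A `concordance_table` object: list with `counts` (integer matrix
#'   with CC/FC dimnames) and `n` (total genes tabulated).
#' @export
cluster_contingency <- function(core_partition, full_partition) {
  core <- core_partition[!is.na(core_partition$community), c("gene", "community")]
  full <- full_partition[!is.na(full_partition$community), c("gene", "community")]
  joined <- dplyr::inner_join(core, full, by = "gene", suffix = c("_core", "_full"))
  n_drop <- nrow(core) - nrow(joined)
  if (nrow(joined) == 0) abort("Core and full partitions share no assigned genes.")
  if (n_drop > 0) {
    inform(sprintf("%d core gene(s) unassigned in the full partition were excluded.", n_drop))
  }
  counts <- table(
    factor(joined$community_core, levels = sort(unique(core$community))),
    factor(joined$community_full, levels = sort(unique(full$community)))
  )
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = list(paste0("CC", rownames(counts)),
                                   paste0("FC", colnames(counts))))
  new_concordance_table(counts)
}

new_concordance_table <- function(counts) {
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts))) rownames(counts) <- paste0("CC", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("FC", seq_len(ncol(counts)))
  structure(list(counts = counts, n = sum(counts)), class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  cat(sprintf("Core/full cluster contingency table (%d x %d, n = %d)\n",
              nrow(x$counts), ncol(x$counts), x$n))
  print(x$counts)
  invisible(x)
}

as_count_matrix <- function(x) {
  if (inherits(x, "concordance_table")) return(x$counts)
  if (is.matrix(x)) return(x)
  if (is.data.frame(x)) return(as.matrix(x))
  abort("Expected a concordance_table, matrix or data frame of counts.")
}

#' Reorder contingency-table columns to concentrate mass on the diagonal
#'
#' Columns are permuted by the maximum-weight assignment of columns to rows
#' (the permutation maximizing the diagonal sum); surplus columns (when there
#' are more columns than rows) are appended in order of descending column
#' sum. Counts are unchanged — this is display/bookkeeping canonicalization
#' only.
#'
#' @param table A `concordance_table` or count matrix.
#' @return The same type of object with columns permuted.
#' @export
reorder_diagonal <- function(table) {
  counts <- as_count_matrix(table)
  r <- nrow(counts)
  k <- ncol(counts)
  m <- min(r, k)
  perm <- if (k <= 8) best_assignment_exhaustive(counts, m) else best_assignment_greedy(counts, m)
  rest <- setdiff(seq_len(k), perm)
  rest <- rest[order(-colSums(counts)[rest])]
  out <- counts[, c(perm, rest), drop = FALSE]
  if (inherits(table, "concordance_table")) new_concordance_table(out) else out
}

best_assignment_exhaustive <- function(counts, m) {
  k <- ncol(counts)
  best <- NULL
  best_sum <- -Inf
  rec <- function(chosen, used) {
    i <- length(chosen) + 1L
    if (i > m) {
      s <- sum(counts[cbind(seq_len(m), chosen)])
      if (s > best_sum) {
        best_sum <<- s
        best <<- chosen
      }
      return(invisible(NULL))
    }
    for (j in seq_len(k)) {
      if (!used[j]) {
        used[j] <- TRUE
        rec(c(chosen, j), used)
        used[j] <- FALSE
      }
    }
  }
  rec(integer(0), logical(k))
  best
}

best_assignment_greedy <- function(counts, m) {
  k <- ncol(counts)
  perm <- integer(m)
  used <- logical(k)
  for (i in seq_len(m)) {
    avail <- which(!used)
    j <- avail[which.max(counts[i, avail])]
    perm[i] <- j
    used[j] <- TRUE
  }
  perm
}

#' Chi-squared statistic of a contingency table
#'
#' The plain (uncorrected) Pearson statistic
#' X^2 = sum_ij (n_ij - e_ij)^2 / e_ij with e_ij = n_i. n_.j / n.
#' Rows and columns whose marginal is zero are dropped first (with a
#' warning) since the expected counts are undefined there.
#'
#' @param table A `concordance_table`, count matrix or data frame.
#' @return The X^2 statistic (a single non-negative number).
#' @export
chi_squared_stat <- function(table) {
  counts <- drop_empty_margins(as_count_matrix(table))
  n <- sum(counts)
  if (n == 0) abort("Contingency table is empty (n = 0).")
  expected <- outer(rowSums(counts), colSums(counts)) / n
  sum((counts - expected)^2 / expected)
}

drop_empty_margins <- function(counts) {
  empty_r <- rowSums(counts) == 0
  empty_c <- colSums(counts) == 0
  if (any(empty_r) || any(empty_c)) {
    warn(sprintf("Dropped %d empty row(s) and %d empty column(s) before X^2/V.",
                 sum(empty_r), sum(empty_c)))
    counts <- counts[!empty_r, !empty_c, drop = FALSE]
  }
  counts
}

#' Cramer's V association between two cluster structures
#'
#' V = sqrt((X^2 / n) / min(k - 1, r - 1)) where k and r are the numbers of
#' (non-empty) columns and rows. V lies in [0, 1]: 0 under exact independence
#' of row and column assignments, 1 when every row maps into a single column
#' (or vice versa). Used here as the core-periphery community concordance
#' measure.
#'
#' @param table A `concordance_table`, count matrix or data frame.
#' @return A one-row tibble: `chi2`, `v`, `df_norm` = min(k-1, r-1), `n`,
#'   `k` (columns), `r` (rows).
#' @export
cramers_v <- function(table) {
  counts <- drop_empty_margins(as_count_matrix(table))
  r <- nrow(counts)
  k <- ncol(counts)
  if (r < 2 || k < 2) {
    abort("Cramer's V requires at least 2 non-empty rows and 2 non-empty columns.")
  }
  chi2 <- chi_squared_stat(counts)
  n <- sum(counts)
  df_norm <- min(k - 1, r - 1)
  v <- sqrt((chi2 / n) / df_norm)
  tibble(chi2 = chi2, v = min(v, 1), df_norm = df_norm, n = n, k = k, r = r)
}

#' Strength-weighted graph-sampling control for the concordance statistic
#'
#' Repeatedly samples `size` nodes without replacement with selection
#' probability proportional to node strength in `edges`, induces the subgraph
#' on the sampled nodes, clusters it, and computes Cramer's V of the induced
#' clustering against `full_partition`. This emulates drawing a "core-sized"
#' strength-biased subgraph from the full network and asks how concordant its
#' community structure is with the full one.
#'
#' A replicate whose induced subgraph has no edges is resampled (up to
#' `max_retries` times, logged) before failing.
#'
#' @param edges Full-network edge tibble.
#' @param size Number of nodes per replicate (the per-tissue core-subgraph
#'   size in the analysis design).
#' @param full_partition Partition of the full network.
#' @param n_replicates Number of sampling replicates (default 10).
#' @param seed Integer seed; replicate i uses seed + i.
#' @param n_restarts Louvain restarts per replicate.
#' @param max_retries Resampling attempts for edgeless replicates.
#' @return A `sampling_control` object: list with `replicates` (tibble of
#'   per-replicate `chi2`, `v`, `n`, `k`, `r`), `mean_v`, `sd_v`, and the
#'   t-based 95% confidence interval (`ci_lower`, `ci_upper`).
#' @export
sample_control <- function(edges, size, full_partition, n_replicates = 10L,
                           seed = 1L, n_restarts = 5L, max_retries = 5L) {
  strengths <- node_strength(edges)
  if (size > nrow(strengths)) abort("`size` exceeds the number of network nodes.")
  reps <- purrr::map(seq_len(n_replicates), function(i) {
    for (try in seq_len(max_retries)) {
      nodes <- withr::with_seed(as.integer(seed) + i * 1000L + try - 1L, {
        sample(strengths$gene, size, prob = strengths$strength)
      })
      sub <- edges[edges[[1]] %in% nodes & edges[[2]] %in% nodes, ]
      if (nrow(sub) > 0) {
        part <- louvain_communities(sub, seed = as.integer(seed) + i,
                                    n_restarts = n_restarts, genes = nodes)
        tab <- cluster_contingency(part, full_partition)
        res <- cramers_v(tab)
        res$replicate <- i
        return(res)
      }
      inform(sprintf("Replicate %d: induced subgraph edgeless, resampling (attempt %d).",
                     i, try))
    }
    abort(sprintf("Replicate %d: induced subgraph edgeless after %d attempts.",
                  i, max_retries))
  })
  replicates <- bind_rows(reps)[, c("replicate", "chi2", "v", "n", "k", "r")]
  new_sampling_control(replicates)
}

new_sampling_control <- function(replicates) {
  v <- replicates$v
  nrep <- nrow(replicates)
  se <- sd(v) / sqrt(nrep)
  crit <- if (nrep > 1) qt(0.975, df = nrep - 1) else NA_real_
  structure(list(
    replicates = replicates,
    n_replicates = nrep,
    mean_v = mean(v),
    sd_v = sd(v),
    ci_lower = mean(v) - crit * se,
    ci_upper = mean(v) + crit * se
  ), class = "sampling_control")
}

#' @export
print.sampling_control <- function(x, ...) {
  cat(sprintf(
    "Graph-sampling control: %d replicates, mean V = %.3f (sd %.3f, 95%% CI [%.3f, %.3f])\n",
    x$n_replicates, x$mean_v, x$sd_v, x$ci_lower, x$ci_upper
  ))
  invisible(x)
}
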