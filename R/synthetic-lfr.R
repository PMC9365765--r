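#' Parameters for the LFR-style weighted benchmark generator
#'
#' Bundles and validates the parameters of the planted-community benchmark:
#' power-law node degrees (exponent `tau_degree`, mean about `avg_degree`,
#' maximum `max_degree`), power-law community sizes (exponent
#' `tau_community`, bounded by `min_comm` and `max_comm`) and a weighted
#' mixing fraction `mu_w` — the expected fraction of each node's incident
#' edge weight that leaves its own community.
#'
#' @param n_nodes Number of nodes.
#' @param avg_degree Target mean degree.
#' @param max_degree Maximum degree.
#' @param tau_degree Degree power-law exponent (default 2).
#' @param tau_community Community-size power-law exponent (default 1.5).
#' @param mu_w Weighted mixing fraction in (0, 1) (default 0.2).
#' @param min_comm,max_comm Community size bounds.
#' @param seed Integer seed.
#' @return A validated `lfr_params` list.
#' @export
lfr_params <- function(n_nodes, avg_degree, max_degree, tau_degree = 2,
                       tau_community = 1.5, mu_w = 0.2, min_comm, max_comm,
                       seed = 1L) {
  p <- list(n_nodes = as.integer(n_nodes), avg_degree = avg_degree,
            max_degree = as.integer(max_degree), tau_degree = tau_degree,
            tau_community = tau_community, mu_w = mu_w,
            min_comm = as.integer(min_comm), max_comm = as.integer(max_comm),
            seed = as.integer(seed))
  if (p$min_comm > p$max_comm) abort("min_comm must be <= max_comm.")
  if (p$max_comm > p$n_nodes) abort("max_comm must be <= n_nodes.")
  if (p$avg_degree > p$max_degree) abort("avg_degree must be <= max_degree.")
  if (p$mu_w <= 0 || p$mu_w >= 1) abort("mu_w must lie strictly between 0 and 1.")
  if (p$avg_degree >= p$min_comm) {
    abort("Infeasible parameters: avg_degree must be below min_comm so internal degrees fit inside communities.")
  }
  structure(p, class = "lfr_params")
}

# inverse-CDF sampler for a continuous truncated power law x^-a on [xmin, xmax]
rplaw <- function(n, a, xmin, xmax) {
  u <- runif(n)
  if (abs(a - 1) < 1e-12) {
    xmin * (xmax / xmin)^u
  } else {
    (xmin^(1 - a) + u * (xmax^(1 - a) - xmin^(1 - a)))^(1 / (1 - a))
  }
}

# mean of the continuous truncated power law
plaw_mean <- function(a, xmin, xmax) {
  num <- if (abs(a - 2) < 1e-12) log(xmax / xmin) else (xmax^(2 - a) - xmin^(2 - a)) / (2 - a)
  den <- if (abs(a - 1) < 1e-12) log(xmax / xmin) else (xmax^(1 - a) - xmin^(1 - a)) / (1 - a)
  num / den
}

# lower truncation point that achieves a target mean
solve_plaw_xmin <- function(a, xmax, target_mean) {
  f <- function(x) plaw_mean(a, x, xmax) - target_mean
  if (f(1) > 0) return(1)
  uniroot(f, c(1, xmax * 0.999), tol = 1e-8)$root
}

#' Generate an LFR-style weighted network with planted communities
#'
#' Native implementation of the Lancichinetti-Fortunato-Radicchi benchmark
#' construction for weighted undirected graphs: community sizes and degrees
#' are drawn from truncated power laws, each node's stubs are split into an
#' internal part (fraction 1 - mu_w, wired inside its community by a
#' configuration-model pairing) and an external part (wired across
#' communities), and edge weights are drawn uniformly on (0.4, 1) so the
#' expected external *weight* fraction per node equals mu_w. Duplicate pairs
#' and self-pairings produced by the stub matching are discarded, which
#' perturbs realized degrees only marginally.
#'
#' @param params An [lfr_params()] object.
#' @return A list with `network` (edge tibble), `truth` (planted partition
#'   tibble) and `params`.
#' @export
generate_lfr <- function(params) {
  stopifnot(inherits(params, "lfr_params"))
  p <- params
  withr::with_seed(p$seed, {
    sizes <- draw_community_sizes(p$n_nodes, p$tau_community, p$min_comm, p$max_comm)
    n <- p$n_nodes
    comm <- rep(seq_along(sizes), sizes)
    node <- sprintf("n%05d", seq_len(n))
    xmin <- solve_plaw_xmin(p$tau_degree, p$max_degree, p$avg_degree)
    d <- pmin(pmax(round(rplaw(n, p$tau_degree, xmin, p$max_degree)), 2L), p$max_degree, n - 1L)
    d_int <- round((1 - p$mu_w) * d)
    d_int <- pmin(d_int, sizes[comm] - 1L)
    d_ext <- d - d_int
    # per-community parity fix: one internal stub moves to the external pool
    for (c_id in seq_along(sizes)) {
      idx <- which(comm == c_id)
      if (sum(d_int[idx]) %% 2 == 1) {
        j <- idx[which.max(d_int[idx])]
        d_int[j] <- d_int[j] - 1L
        d_ext[j] <- d_ext[j] + 1L
      }
    }
    seen <- new.env(hash = TRUE, parent = emptyenv())
    ea <- integer(0)
    eb <- integer(0)
    add_pairs <- function(p1, p2) {
      keep <- logical(length(p1))
      for (i in seq_along(p1)) {
        a <- min(p1[i], p2[i])
        b <- max(p1[i], p2[i])
        key <- paste0(a, "_", b)
        if (a != b && is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          keep[i] <- TRUE
        }
      }
      ea <<- c(ea, pmin(p1[keep], p2[keep]))
      eb <<- c(eb, pmax(p1[keep], p2[keep]))
      keep
    }
    # internal configuration-model pairing, community by community
    for (c_id in seq_along(sizes)) {
      idx <- which(comm == c_id)
      stubs <- rep(idx, d_int[idx])
      stubs <- sample(stubs)
      half <- length(stubs) %/% 2
      add_pairs(stubs[seq_len(half)], stubs[half + seq_len(half)])
    }
    # external pairing with rewiring: recycle stubs from rejected pairs
    stubs <- rep(seq_len(n), d_ext)
    if (length(stubs) %% 2 == 1) stubs <- stubs[-sample(length(stubs), 1)]
    for (round in seq_len(30)) {
      if (length(stubs) < 2) break
      stubs <- sample(stubs)
      half <- length(stubs) %/% 2
      p1 <- stubs[seq_len(half)]
      p2 <- stubs[half + seq_len(half)]
      cross <- comm[p1] != comm[p2]
      ok <- cross
      ok[cross] <- add_pairs(p1[cross], p2[cross])
      stubs <- c(p1[!ok], p2[!ok])
      if (!any(ok)) break
    }
    w <- runif(length(ea), 0.4, 1)
    net <- tibble(gene_a = node[ea], gene_b = node[eb], weight = w)
    swap <- net$gene_a > net$gene_b
    tmp <- net$gene_a[swap]
    net$gene_a[swap] <- net$gene_b[swap]
    net$gene_b[swap] <- tmp
    net <- arrange(net, .data$gene_a, .data$gene_b)
    truth <- new_partition(node, comm)
    truth <- arrange(truth, .data$gene)
    list(network = net, truth = new_partition(truth$gene, truth$community), params = p)
  })
}

draw_community_sizes <- function(n, tau, minc, maxc) {
  sizes <- integer(0)
  while (sum(sizes) < n) {
    sizes <- c(sizes, as.integer(round(rplaw(1, tau, minc, maxc))))
  }
  excess <- sum(sizes) - n
  last <- sizes[length(sizes)] - excess
  if (last >= minc) {
    sizes[length(sizes)] <- last
  } else {
    sizes <- sizes[-length(sizes)]
    deficit <- n - sum(sizes)
    if (length(sizes) == 0) abort("Infeasible community-size parameters for this n_nodes.")
    add <- rep(deficit %/% length(sizes), length(sizes))
    add[seq_len(deficit %% length(sizes))] <- add[seq_len(deficit %% length(sizes))] + 1L
    sizes <- sizes + add
  }
  sizes
}

#' Per-node external weight fraction of a planted network
#'
#' Diagnostic for the realized weighted mixing: for each node, the fraction
#' of its strength carried by edges leaving its planted community.
#'
#' @param network Edge tibble.
#' @param truth Planted partition tibble.
#' @return A tibble with columns `gene` and `external_fraction`.
#' @export
external_weight_fraction <- function(network, truth) {
  comm <- setNames(truth$community, truth$gene)
  cross <- comm[network$gene_a] != comm[network$gene_b]
  tot <- node_strength(network, genes = truth$gene)
  ext <- node_strength(network[cross, ], genes = truth$gene)
  tibble(gene = tot$gene,
         external_fraction = ifelse(tot$strength > 0, ext$strength / tot$strength, 0))
}

#' Select benchmark nodes by strength regime
#'
#' `top_strength` picks the `size` highest-strength nodes (ties broken by
#' node id); `distribution_matched` picks a uniform random sample, which
#' reproduces the full strength distribution in expectation.
#'
#' @param edges Edge tibble of the network to sample from.
#' @param mode `"top_strength"` or `"distribution_matched"`.
#' @param size Number of nodes to select.
#' @param seed Seed for the random mode.
#' @return Character vector of selected node ids.
#' @export
select_nodes <- function(edges, mode = c("top_strength", "distribution_matched"),
                         size, seed = 1L) {
  mode <- match.arg(mode)
  strengths <- node_strength(edges)
  if (size > nrow(strengths)) abort("`size` exceeds the number of nodes.")
  if (mode == "top_strength") {
    ord <- order(-strengths$strength, strengths$gene)
    strengths$gene[ord][seq_len(size)]
  } else {
    withr::with_seed(as.integer(seed), sample(strengths$gene, size))
  }
}

#' Benchmark calibration of the concordance statistic
#'
#' Generates a planted-community benchmark network and measures Cramer's V
#' between the planted partition and the detected communities of (a) the
#' induced subgraph on the top-strength nodes (one deterministic selection)
#' and (b) induced subgraphs on uniformly sampled node sets
#' (`n_replicates` replicates). Strong nodes retain the community structure
#' (V close to 1); distribution-matched samples yield lower V — the ordering
#' v_strong > mean(v_avg) is the calibration property of the statistic.
#'
#' @param params An [lfr_params()] object.
#' @param size Number of nodes to select per subgraph.
#' @param n_replicates Replicates for the distribution-matched mode.
#' @param seed Seed for selection and clustering.
#' @param n_restarts Louvain restarts per clustering.
#' @return A list with `v_strong` (one-row [cramers_v()] tibble), `v_avg`
#'   (a `sampling_control` over the replicates), `network` and `truth`.
#' @export
benchmark_calibration <- function(params, size, n_replicates = 10L, seed = 1L,
                                  n_restarts = 10L) {
  pl <- generate_lfr(params)
  v_strong <- subgraph_concordance(pl$network, pl$truth,
                                   select_nodes(pl$network, "top_strength", size),
                                   seed = seed, n_restarts = n_restarts)
  reps <- purrr::map(seq_len(n_replicates), function(i) {
    nodes <- select_nodes(pl$network, "distribution_matched", size,
                          seed = as.integer(seed) + 7000L + i)
    res <- subgraph_concordance(pl$network, pl$truth, nodes,
                                seed = as.integer(seed) + i, n_restarts = n_restarts)
    res$replicate <- i
    res
  })
  replicates <- bind_rows(reps)[, c("replicate", "chi2", "v", "n", "k", "r")]
  list(v_strong = v_strong, v_avg = new_sampling_control(replicates),
       network = pl$network, truth = pl$truth)
}

# cluster the induced subgraph on `nodes` and score it against `reference`
subgraph_concordance <- function(edges, reference, nodes, seed = 1L, n_restarts = 10L) {
  sub <- edges[edges[[1]] %in% nodes & edges[[2]] %in% nodes, ]
  part <- if (nrow(sub) == 0) {
    new_partition(nodes, seq_along(nodes))
  } else {
    louvain_communities(sub, seed = seed, n_restarts = n_restarts, genes = nodes)
  }
  cramers_v(cluster_contingency(part, reference))
}
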