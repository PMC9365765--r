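#' Simulate a tissue-specific weighted network with a planted core-gene set
#'
#' Emulates the qualitative contrast between disorder-relevant and
#' irrelevant tissues: communities are planted as equal-sized blocks with
#' strong internal and weak external edges, each community carries a
#' high-strength "hub" stratum, and core genes are placed according to
#' `concordance`. With probability `concordance` a core gene occupies a hub
#' slot (cycling over communities, its core-core edges within the community
#' up-weighted) — the relevant-tissue regime in which core genes are both
#' strength-central and community-aligned. Otherwise it is placed uniformly
#' at random and connected to other scattered cores only by sparse weak
#' edges — the irrelevant-tissue regime.
#'
#' @param n_nodes Number of genes (default 800).
#' @param n_communities Number of planted communities (default 4).
#' @param core_size Number of core genes (default 80).
#' @param concordance Probability in [0, 1] that a core gene is planted in
#'   the aligned, high-strength regime (1 = fully relevant tissue, 0 = fully
#'   scattered).
#' @param avg_internal_degree,avg_external_degree Mean within/between
#'   community degree of the background graph (defaults 12 and 3).
#' @param hub_fraction Fraction of each community reserved as the hub
#'   stratum (default 0.25).
#' @param hub_boost Extra within-community edges attached to each hub
#'   (default 10).
#' @param seed Integer seed.
#' @return A list with `network` (edge tibble), `core` (character vector of
#'   core genes) and `truth` (planted partition).
#' @export
generate_tissue <- function(n_nodes = 800L, n_communities = 4L, core_size = 80L,
                            concordance = 1, avg_internal_degree = 12,
                            avg_external_degree = 3, hub_fraction = 0.25,
                            hub_boost = 10L, seed = 1L) {
  if (core_size <= 0) abort("core_size must be positive.")
  if (concordance < 0 || concordance > 1) abort("concordance must lie in [0, 1].")
  if (core_size > n_nodes) abort("core_size must be <= n_nodes.")
  n_nodes <- as.integer(n_nodes)
  n_communities <- as.integer(n_communities)
  base <- n_nodes %/% n_communities
  sizes <- rep(base, n_communities)
  sizes[seq_len(n_nodes - base * n_communities)] <-
    sizes[seq_len(n_nodes - base * n_communities)] + 1L
  hub_cap <- sum(pmax(1L, floor(sizes * hub_fraction)))
  if (core_size > hub_cap) {
    abort(sprintf("core_size (%d) exceeds hub stratum capacity (%d); increase n_nodes or hub_fraction.",
                  core_size, hub_cap))
  }
  withr::with_seed(as.integer(seed), {
    comm <- rep(seq_len(n_communities), sizes)
    gene <- sprintf("g%04d", seq_len(n_nodes))
    edges <- list()
    # background block model: strong internal, weak external edges
    for (c_id in seq_len(n_communities)) {
      idx <- which(comm == c_id)
      p_in <- min(1, avg_internal_degree / (length(idx) - 1))
      pairs <- random_pairs(idx, idx, p_in)
      if (nrow(pairs) > 0) {
        edges[[length(edges) + 1]] <- tibble(
          a = pairs[, 1], b = pairs[, 2], weight = runif(nrow(pairs), 0.5, 1)
        )
      }
    }
    for (c_id in seq_len(n_communities - 1L)) {
      for (c2 in seq((c_id + 1L), n_communities)) {
        i1 <- which(comm == c_id)
        i2 <- which(comm == c2)
        p_out <- min(1, avg_external_degree / (n_nodes - length(i1)))
        pairs <- random_pairs(i1, i2, p_out)
        if (nrow(pairs) > 0) {
          edges[[length(edges) + 1]] <- tibble(
            a = pairs[, 1], b = pairs[, 2], weight = runif(nrow(pairs), 0.05, 0.3)
          )
        }
      }
    }
    # hub stratum: first slots of each community get extra internal edges
    hubs <- unlist(lapply(seq_len(n_communities), function(c_id) {
      idx <- which(comm == c_id)
      idx[seq_len(max(1L, floor(length(idx) * hub_fraction)))]
    }))
    hub_a <- integer(0)
    hub_b <- integer(0)
    for (h in hubs) {
      others <- setdiff(which(comm == comm[h]), h)
      tgt <- sample(others, min(hub_boost, length(others)))
      hub_a <- c(hub_a, rep(h, length(tgt)))
      hub_b <- c(hub_b, tgt)
    }
    edges[[length(edges) + 1]] <- tibble(a = hub_a, b = hub_b,
                                         weight = runif(length(hub_a), 0.6, 1))
    # core placement
    aligned <- runif(core_size) < concordance
    hub_pool <- split(hubs, comm[hubs])
    core_idx <- integer(core_size)
    pool_pos <- rep(1L, n_communities)
    next_comm <- 1L
    for (i in seq_len(core_size)) {
      if (aligned[i]) {
        tries <- 0L
        while (pool_pos[next_comm] > length(hub_pool[[next_comm]]) && tries < n_communities) {
          next_comm <- next_comm %% n_communities + 1L
          tries <- tries + 1L
        }
        core_idx[i] <- hub_pool[[next_comm]][pool_pos[next_comm]]
        pool_pos[next_comm] <- pool_pos[next_comm] + 1L
        next_comm <- next_comm %% n_communities + 1L
      }
    }
    free <- setdiff(seq_len(n_nodes), core_idx)
    core_idx[!aligned] <- sample(free, sum(!aligned))
    # core-core edges: aligned cores in the same community are strongly tied,
    # scattered cores only sparsely and weakly
    ca <- integer(0); cb <- integer(0); cw <- numeric(0)
    al_idx <- core_idx[aligned]
    if (length(al_idx) > 1) {
      for (c_id in seq_len(n_communities)) {
        members <- al_idx[comm[al_idx] == c_id]
        if (length(members) > 1) {
          pairs <- random_pairs(members, members, 0.6)
          ca <- c(ca, pairs[, 1]); cb <- c(cb, pairs[, 2])
          cw <- c(cw, runif(nrow(pairs), 0.7, 1))
        }
      }
    }
    sc_idx <- core_idx[!aligned]
    if (length(sc_idx) > 1) {
      pairs <- random_pairs(sc_idx, sc_idx, min(1, 4 / length(sc_idx)))
      ca <- c(ca, pairs[, 1]); cb <- c(cb, pairs[, 2])
      cw <- c(cw, runif(nrow(pairs), 0.05, 0.15))
    }
    if (length(ca) > 0) {
      edges[[length(edges) + 1]] <- tibble(a = ca, b = cb, weight = cw)
    }
    all_edges <- bind_rows(edges)
    net <- suppressMessages(suppressWarnings(as_gene_network(
      tibble(gene_a = gene[all_edges$a], gene_b = gene[all_edges$b],
             weight = all_edges$weight)
    )))
    list(network = net, core = gene[core_idx], truth = new_partition(gene, comm))
  })
}

# unordered random pairs between two index sets with inclusion probability p
random_pairs <- function(set1, set2, p) {
  if (identical(set1, set2)) {
    n <- length(set1)
    if (n < 2) return(matrix(integer(0), ncol = 2))
    idx <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    keep <- runif(nrow(idx)) < p
    cbind(set1[idx[keep, 1]], set1[idx[keep, 2]])
  } else {
    grid <- expand.grid(i = set1, j = set2)
    keep <- runif(nrow(grid)) < p
    cbind(grid$i[keep], grid$j[keep])
  }
}

#' Simulate annotation gene sets aligned with planted clusters
#'
#' Builds a GMT-like annotation table over the genes of `truth`: "signal"
#' terms draw at least `signal_purity` of their members from a single home
#' cluster (so they are enriched in it by construction), "noise" terms draw
#' uniformly from the whole universe.
#'
#' @param truth A partition tibble defining the gene universe and clusters.
#' @param n_terms Total number of terms (default 30).
#' @param signal_terms_per_cluster Signal terms per cluster (default 2).
#' @param term_size_range Inclusive bounds on term sizes (default 10-40).
#' @param signal_purity Fraction of a signal term drawn from its home
#'   cluster (default 0.8).
#' @param seed Integer seed.
#' @return An annotation tibble as from [read_gmt()], with an extra
#'   `home_cluster` column (NA for noise terms).
#' @export
generate_annotations <- function(truth, n_terms = 30L,
                                 signal_terms_per_cluster = 2L,
                                 term_size_range = c(10L, 40L),
                                 signal_purity = 0.8, seed = 1L) {
  clusters <- sort(unique(truth$community[!is.na(truth$community)]))
  n_signal <- length(clusters) * signal_terms_per_cluster
  if (n_terms < n_signal) abort("n_terms must be >= the number of signal terms.")
  universe <- truth$gene
  withr::with_seed(as.integer(seed), {
    rows <- purrr::map(seq_len(n_terms), function(i) {
      size <- sample(seq(term_size_range[1], term_size_range[2]), 1)
      size <- min(size, length(universe))
      if (i <= n_signal) {
        home <- clusters[((i - 1L) %% length(clusters)) + 1L]
        members <- truth$gene[!is.na(truth$community) & truth$community == home]
        n_home <- min(length(members), ceiling(signal_purity * size))
        other <- setdiff(universe, members)
        genes <- c(sample(members, n_home),
                   sample(other, min(size - n_home, length(other))))
        tibble(term_id = sprintf("TERM%04d", i),
               term_name = sprintf("signal term %d (cluster %d)", i, home),
               genes = list(unique(genes)), home_cluster = home)
      } else {
        tibble(term_id = sprintf("TERM%04d", i),
               term_name = sprintf("noise term %d", i),
               genes = list(unique(sample(universe, size))),
               home_cluster = NA_integer_)
      }
    })
    out <- bind_rows(rows)
    out$n_genes <- lengths(out$genes)
    out[, c("term_id", "term_name", "genes", "n_genes", "home_cluster")]
  })
}

#' Simulate a subject phenotype table with planted subcluster effects
#'
#' Each subject receives a Poisson number of disruptive-variant genes drawn
#' uniformly from the gene universe. A trait value is the baseline plus the
#' sum of the planted shifts of every subcluster the subject carries a
#' variant in, plus Gaussian noise. Planted shifts are recoverable by
#' carrier/non-carrier group comparison.
#'
#' @param cell_genes Named list mapping subcluster id to its gene set; the
#'   union is the variant universe.
#' @param n_subjects Number of subjects (default 3000).
#' @param baseline_iq,baseline_walk Baseline IQ (points) and age of walking
#'   (months).
#' @param iq_shift,walk_shift Named numeric vectors of per-subcluster trait
#'   shifts (names must be subcluster ids; missing cells shift 0). Shifts
#'   are added to carriers, so a negative `iq_shift` plants an IQ deficit.
#' @param iq_sd,walk_sd Gaussian noise standard deviations (defaults 15
#'   points, 2 months).
#' @param mean_variants Mean disruptive variants per subject (default 1).
#' @param seed Integer seed.
#' @return A subject tibble (`subject_id`, `iq`, `age_of_walking`,
#'   `disruptive_genes` list column).
#' @export
generate_phenotypes <- function(cell_genes, n_subjects = 3000L,
                                baseline_iq = 100, baseline_walk = 13,
                                iq_shift = numeric(0), walk_shift = numeric(0),
                                iq_sd = 15, walk_sd = 2, mean_variants = 1,
                                seed = 1L) {
  if (n_subjects <= 0) abort("n_subjects must be positive.")
  if (iq_sd <= 0 || walk_sd <= 0) abort("Noise standard deviations must be positive.")
  universe <- unique(unlist(cell_genes))
  withr::with_seed(as.integer(seed), {
    hits <- lapply(rpois(n_subjects, mean_variants), function(k) {
      if (k == 0) character(0) else unique(sample(universe, min(k, length(universe))))
    })
    shift_for <- function(shifts) {
      vapply(hits, function(g) {
        if (length(g) == 0) return(0)
        carried <- vapply(names(cell_genes), function(cell) {
          any(g %in% cell_genes[[cell]])
        }, logical(1))
        sum(shifts[names(cell_genes)[carried]], na.rm = TRUE)
      }, numeric(1))
    }
    iq_eff <- shift_for(iq_shift)
    walk_eff <- shift_for(walk_shift)
    tibble(
      subject_id = sprintf("s%05d", seq_len(n_subjects)),
      iq = baseline_iq + iq_eff + rnorm(n_subjects, 0, iq_sd),
      age_of_walking = baseline_walk + walk_eff + rnorm(n_subjects, 0, walk_sd),
      disruptive_genes = hits
    )
  })
}
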