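#' Upper-tail hypergeometric probability
#'
#' P(X >= b) where X counts term genes in a size-`n` target drawn from a
#' size-`N` background containing `B` term genes. This is the fixed
#' target-vs-background enrichment test.
#'
#' @param N Background size.
#' @param B Term genes in the background.
#' @param n Target size.
#' @param b Term genes in the target.
#' @return The upper-tail probability.
#' @export
hypergeom_upper <- function(N, B, n, b) {
  if (B > N || n > N) abort("Require B <= N and n <= N.")
  if (b > min(B, n)) abort("Require b <= min(B, n).")
  if (b < 0) abort("b must be non-negative.")
  if (b == 0) return(1)
  phyper(b - 1, m = B, n = N - B, k = n, lower.tail = FALSE)
}

#' Enrichment fold of a term in a target gene set
#'
#' (b / n) / (B / N): the term's frequency in the target over its frequency
#' in the background.
#'
#' @inheritParams hypergeom_upper
#' @return The fold ratio.
#' @export
enrichment_fold <- function(N, B, n, b) {
  if (n <= 0) abort("Target size n must be positive.")
  if (B <= 0) abort("Enrichment fold undefined for a term absent from the background (B = 0).")
  if (b > min(B, n)) abort("Require b <= min(B, n).")
  (b / n) / (B / N)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment, returned in input order.
#'
#' @param p Vector of p-values in [0, 1].
#' @return Vector of q-values, `q >= p`, capped at 1.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "BH")
}

#' Hypergeometric gene-set enrichment of a target against a background
#'
#' One record per annotation term with at least one background gene; the
#' overlap `b`, fold, upper-tail hypergeometric p and BH q-value (adjusted
#' across all terms tested for this target). Genes without any annotation
#' still count toward the background size N and target size n. A term is
#' significant when `p < p_cut` and `q < q_cut`.
#'
#' @param target Character vector of target genes (must be a subset of
#'   `background`).
#' @param background Character vector of background genes.
#' @param annotations Annotation tibble (see [read_gmt()]).
#' @param p_cut,q_cut Significance cut-offs (defaults 0.001 and 0.05, the
#'   conventional webtool defaults for this test).
#' @return A tibble with columns `term_id`, `term_name`, `N`, `B`, `n`, `b`,
#'   `fold`, `p`, `q`, `significant` and `hit_genes` (list column of target
#'   genes in the term), sorted by `q` then `p`.
#' @export
enrich_cluster <- function(target, background, annotations,
                           p_cut = 0.001, q_cut = 0.05) {
  target <- unique(as.character(target))
  background <- unique(as.character(background))
  if (length(target) == 0) abort("Target gene set is empty.")
  if (!all(target %in% background)) {
    abort("Target must be a subset of the background gene set.")
  }
  N <- length(background)
  n <- length(target)
  rows <- purrr::map(seq_len(nrow(annotations)), function(i) {
    term_bg <- intersect(annotations$genes[[i]], background)
    B <- length(term_bg)
    if (B == 0) return(NULL)
    hits <- intersect(term_bg, target)
    b <- length(hits)
    tibble(
      term_id = annotations$term_id[i],
      term_name = annotations$term_name[i],
      N = N, B = B, n = n, b = b,
      fold = enrichment_fold(N, B, n, b),
      p = hypergeom_upper(N, B, n, b),
      hit_genes = list(hits)
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(term_id = character(), term_name = character(), N = integer(),
                  B = integer(), n = integer(), b = integer(), fold = numeric(),
                  p = numeric(), q = numeric(), significant = logical(),
                  hit_genes = list()))
  }
  out$q <- bh_fdr(out$p)
  out$significant <- out$p < p_cut & out$q < q_cut
  out[order(out$q, out$p, out$term_id),
      c("term_id", "term_name", "N", "B", "n", "b", "fold", "p", "q",
        "significant", "hit_genes")]
}

#' Per-cell enrichment summaries
#'
#' For each cell (a core cluster or a core-by-full subcluster), counts the
#' unique genes covered by its significant terms, the number of significant
#' terms, and the median -log10(q) over those terms (NA when none).
#'
#' @param cell_genes Named list mapping cell id to its member genes.
#' @param cell_records Named list mapping cell id to its [enrich_cluster()]
#'   result.
#' @return A tibble with columns `cell`, `genes_total`, `genes_enriched`,
#'   `enriched_ratio`, `n_terms`, `median_neglog_q`.
#' @export
summarize_cells <- function(cell_genes, cell_records) {
  rows <- purrr::map(names(cell_genes), function(cell) {
    members <- unique(cell_genes[[cell]])
    rec <- cell_records[[cell]]
    sig <- if (is.null(rec) || nrow(rec) == 0) rec else rec[rec$significant, ]
    if (is.null(sig) || nrow(sig) == 0) {
      return(tibble(cell = cell, genes_total = length(members),
                    genes_enriched = 0L, enriched_ratio = 0,
                    n_terms = 0L, median_neglog_q = NA_real_))
    }
    enriched <- intersect(unique(unlist(sig$hit_genes)), members)
    tibble(
      cell = cell,
      genes_total = length(members),
      genes_enriched = length(enriched),
      enriched_ratio = length(enriched) / length(members),
      n_terms = nrow(sig),
      median_neglog_q = median(-log10(sig$q))
    )
  })
  bind_rows(rows)
}

#' Regrouping null control for cluster enrichment
#'
#' Randomly permutes the gene-to-cluster assignment (preserving cluster
#' sizes), reruns the enrichment of every pseudo-cluster against the same
#' background, and records the total number of significant terms and the
#' unique count of enriched genes per replicate. Functionally coherent
#' clusters should far exceed this null.
#'
#' @param partition Partition tibble of the core genes (gene, community).
#' @param annotations Annotation tibble.
#' @param n_replicates Number of regrouping replicates (default 10).
#' @param seed Integer seed.
#' @param p_cut,q_cut Significance cut-offs passed to [enrich_cluster()].
#' @return A `regroup_control` object: list with `replicates` (tibble of
#'   `replicate`, `n_terms`, `genes_enriched`), means and t-based 95% CIs.
#' @export
regroup_control <- function(partition, annotations, n_replicates = 10L,
                            seed = 1L, p_cut = 0.001, q_cut = 0.05) {
  stopifnot(n_replicates >= 1)
  assigned <- partition[!is.na(partition$community), ]
  background <- assigned$gene
  rows <- purrr::map(seq_len(n_replicates), function(i) {
    shuffled <- withr::with_seed(as.integer(seed) + i, sample(assigned$community))
    n_terms <- 0L
    enriched <- character(0)
    for (cl in sort(unique(shuffled))) {
      members <- assigned$gene[shuffled == cl]
      rec <- enrich_cluster(members, background, annotations,
                            p_cut = p_cut, q_cut = q_cut)
      sig <- rec[rec$significant, ]
      n_terms <- n_terms + nrow(sig)
      if (nrow(sig) > 0) {
        enriched <- union(enriched, intersect(unique(unlist(sig$hit_genes)), members))
      }
    }
    tibble(replicate = i, n_terms = n_terms, genes_enriched = length(enriched))
  })
  replicates <- bind_rows(rows)
  ci <- function(x) {
    if (n_replicates > 1) {
      m <- mean(x)
      half <- qt(0.975, df = n_replicates - 1) * sd(x) / sqrt(n_replicates)
      c(m - half, m + half)
    } else c(NA_real_, NA_real_)
  }
  ci_t <- ci(replicates$n_terms)
  ci_g <- ci(replicates$genes_enriched)
  structure(list(
    replicates = replicates,
    mean_terms = mean(replicates$n_terms),
    mean_genes = mean(replicates$genes_enriched),
    ci_terms = ci_t, ci_genes = ci_g
  ), class = "regroup_control")
}

#' @export
print.regroup_control <- function(x, ...) {
  cat(sprintf(
    "Regrouping control: %d replicates; %.1f significant terms (95%% CI [%.1f, %.1f]), %.1f enriched genes (95%% CI [%.1f, %.1f]) per replicate.\n",
    nrow(x$replicates), x$mean_terms, x$ci_terms[1], x$ci_terms[2],
    x$mean_genes, x$ci_genes[1], x$ci_genes[2]
  ))
  invisible(x)
}

#' Cramer's V on the distribution of significant terms over subclusters
#'
#' Arranges per-cell significant-term counts into the core-by-full cluster
#' grid and applies the chi-squared / Cramer's V machinery, measuring
#' whether functional annotation concentrates along the same core-full
#' alignment as the genes themselves.
#'
#' @param cell_terms A tibble with columns `core_cluster`, `full_cluster`
#'   and `n_terms` (one row per cell).
#' @return A one-row [cramers_v()] tibble.
#' @export
term_table_v <- function(cell_terms) {
  tab <- tidyr::pivot_wider(
    cell_terms[, c("core_cluster", "full_cluster", "n_terms")],
    names_from = "full_cluster", values_from = "n_terms", values_fill = 0
  )
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- paste0("CC", tab$core_cluster)
  colnames(m) <- paste0("FC", colnames(m))
  cramers_v(m)
}
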