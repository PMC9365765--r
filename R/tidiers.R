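#' Tidy a community partition
#'
#' @param x A `gene_partition`.
#' @param ... Unused.
#' @return A plain tibble with columns `gene` and `community`.
#' @export
tidy.gene_partition <- function(x, ...) {
  tibble(gene = x$gene, community = x$community)
}

#' One-row summary of a community partition
#'
#' @param x A `gene_partition`.
#' @param ... Unused.
#' @return A tibble with `n_genes`, `n_communities`, `n_unassigned`,
#'   `modularity`.
#' @export
glance.gene_partition <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_communities = length(unique(x$community[!is.na(x$community)])),
    n_unassigned = sum(is.na(x$community)),
    modularity = attr(x, "modularity") %||% NA_real_
  )
}

#' Tidy a core/full contingency table into long form
#'
#' @param x A `concordance_table`.
#' @param ... Unused.
#' @return A tibble with columns `core_cluster`, `full_cluster`, `count`.
#' @export
tidy.concordance_table <- function(x, ...) {
  df <- as.data.frame(as.table(x$counts), stringsAsFactors = FALSE)
  names(df) <- c("core_cluster", "full_cluster", "count")
  as_tibble(df)
}

#' One-row summary of a contingency table: its association statistics
#'
#' @param x A `concordance_table`.
#' @param ... Unused.
#' @return The one-row [cramers_v()] tibble for the table.
#' @export
glance.concordance_table <- function(x, ...) {
  cramers_v(x)
}

#' Per-replicate values of a graph-sampling control
#'
#' @param x A `sampling_control`.
#' @param ... Unused.
#' @return The replicate tibble (`replicate`, `chi2`, `v`, `n`, `k`, `r`).
#' @export
tidy.sampling_control <- function(x, ...) {
  x$replicates
}

#' One-row summary of a graph-sampling control
#'
#' @param x A `sampling_control`.
#' @param ... Unused.
#' @return A tibble with `n_replicates`, `mean_v`, `sd_v`, `ci_lower`,
#'   `ci_upper`.
#' @export
glance.sampling_control <- function(x, ...) {
  tibble(n_replicates = x$n_replicates, mean_v = x$mean_v, sd_v = x$sd_v,
         ci_lower = x$ci_lower, ci_upper = x$ci_upper)
}

#' Per-replicate values of a regrouping control
#'
#' @param x A `regroup_control`.
#' @param ... Unused.
#' @return The replicate tibble (`replicate`, `n_terms`, `genes_enriched`).
#' @export
tidy.regroup_control <- function(x, ...) {
  x$replicates
}

#' One-row summary of a regrouping control
#'
#' @param x A `regroup_control`.
#' @param ... Unused.
#' @return A tibble with replicate means and 95% confidence bounds.
#' @export
glance.regroup_control <- function(x, ...) {
  tibble(
    n_replicates = nrow(x$replicates),
    mean_terms = x$mean_terms, terms_ci_lower = x$ci_terms[1],
    terms_ci_upper = x$ci_terms[2],
    mean_genes = x$mean_genes, genes_ci_lower = x$ci_genes[1],
    genes_ci_upper = x$ci_genes[2]
  )
}
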