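#' Heatmap of a core/full cluster contingency table
#'
#' Tiles are shaded by gene count and annotated with the counts, rows are
#' core-subgraph clusters, columns full-network clusters. Apply
#' [reorder_diagonal()] first to concentrate mass on the diagonal.
#'
#' @param object A `concordance_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.concordance_table <- function(object, ...) {
  df <- tidy(object)
  df$core_cluster <- factor(df$core_cluster, levels = rev(rownames(object$counts)))
  df$full_cluster <- factor(df$full_cluster, levels = colnames(object$counts))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$full_cluster, y = .data$core_cluster,
                                   fill = .data$count)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "Full-network cluster", y = "Core-subgraph cluster",
                  fill = "Genes") +
    ggplot2::theme_minimal()
}

#' Replicate Cramer's V values of a sampling control
#'
#' Points per replicate with the mean and its 95% confidence band.
#'
#' @param object A `sampling_control`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sampling_control <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$replicate), y = .data$v)) +
    ggplot2::geom_hline(yintercept = object$mean_v, linetype = 2, color = "grey40") +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = object$ci_lower, ymax = object$ci_upper,
                      alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Replicate", y = "Cramer's V") +
    ggplot2::theme_minimal()
}

#' Strength distributions of core versus peripheral genes
#'
#' Empirical cumulative distributions of node strength for the core gene
#' set and the remaining (peripheral) genes — the visual counterpart of the
#' centrality test.
#'
#' @param strengths A strength tibble from [node_strength()].
#' @param core Character vector of core gene identifiers.
#' @return A ggplot object.
#' @export
plot_strength_ecdf <- function(strengths, core) {
  df <- mutate(strengths,
               group = ifelse(.data$gene %in% core, "core", "peripheral"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$strength, color = .data$group)) +
    ggplot2::stat_ecdf(linewidth = 0.8) +
    ggplot2::labs(x = "Node strength", y = "Cumulative fraction",
                  color = NULL) +
    ggplot2::theme_minimal()
}
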