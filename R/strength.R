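#' Node strength of a weighted network
#'
#' Strength generalizes degree to weighted graphs: the sum of the weights of
#' a node's incident edges. The sum of all strengths equals twice the total
#' edge weight.
#'
#' @param edges A gene network edge tibble (see [as_gene_network()]).
#' @param genes Optional character vector of genes to report. Genes with no
#'   incident edge get strength 0. Defaults to the genes present in `edges`.
#' @return A tibble with columns `gene` and `strength`, one row per gene,
#'   sorted by gene.
#' @export
node_strength <- function(edges, genes = NULL) {
  ga <- as.character(edges[[1]])
  gb <- as.character(edges[[2]])
  w <- as.numeric(edges[[3]])
  genes <- if (is.null(genes)) sort(unique(c(ga, gb))) else sort(unique(as.character(genes)))
  s <- setNames(numeric(length(genes)), genes)
  if (length(w) > 0) {
    agg <- rowsum(c(w, w), group = c(ga, gb))
    hit <- intersect(rownames(agg), genes)
    s[hit] <- agg[hit, 1]
  }
  tibble(gene = genes, strength = unname(s))
}

#' Test whether core genes are central (higher strength) in one tissue
#'
#' Two-sided Mann-Whitney U test of core-gene strengths against all remaining
#' (peripheral) gene strengths. The exact null distribution is used when both
#' groups have at most 20 untied observations; otherwise the tie-corrected
#' normal approximation (no continuity correction). Core genes are declared
#' central only when the test is significant *and* the core median strength
#' exceeds the peripheral median — significance in the wrong direction never
#' counts as centrality.
#'
#' @param strengths A strength tibble from [node_strength()].
#' @param core Character vector of core gene identifiers.
#' @param alpha Significance cut-off (default 0.05).
#' @param tissue Optional tissue name carried into the result.
#' @return A one-row tibble: `tissue`, `n_core`, `n_peripheral`,
#'   `u_statistic`, `p_value`, `core_median`, `peripheral_median`,
#'   `core_central`.
#' @export
centrality_test <- function(strengths, core, alpha = 0.05, tissue = NA_character_) {
  core <- as.character(core)
  is_core <- strengths$gene %in% core
  x <- strengths$strength[is_core]
  y <- strengths$strength[!is_core]
  if (length(x) == 0) abort("Core group is empty: no core gene is present in the network.")
  if (length(y) == 0) abort("Peripheral group is empty: every network gene is a core gene.")
  if (length(unique(c(x, y))) == 1) {
    abort("Degenerate strength distributions: all values tied across core and peripheral groups.")
  }
  exact <- max(length(x), length(y)) <= 20 && !anyDuplicated(c(x, y))
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact, correct = FALSE)
  )
  med_x <- median(x)
  med_y <- median(y)
  tibble(
    tissue = tissue,
    n_core = length(x),
    n_peripheral = length(y),
    u_statistic = unname(ht$statistic),
    p_value = ht$p.value,
    core_median = med_x,
    peripheral_median = med_y,
    core_central = ht$p.value < alpha && med_x > med_y
  )
}

#' Brain vs non-brain enrichment of tissues where core genes are central
#'
#' Cross-tabulates per-tissue centrality calls against brain-related labels
#' and reports the enrichment factor
#' (central_brain / total_brain) / (central_nonbrain / total_nonbrain)
#' together with the uncorrected chi-squared statistic of the 2x2 table
#' (df = 1).
#'
#' @param results A tibble of per-tissue [centrality_test()] rows.
#' @param labels A tissue label tibble (see [read_tissue_labels()]).
#' @return A one-row tibble with the four cell counts, `enrichment_factor`,
#'   `chi2` and `p_value`.
#' @export
tissue_enrichment <- function(results, labels) {
  joined <- left_join(results, labels, by = "tissue")
  if (anyNA(joined$brain_related)) {
    abort(sprintf("No brain/non-brain label for tissue(s): %s",
                  paste(joined$tissue[is.na(joined$brain_related)], collapse = ", ")))
  }
  cb <- sum(joined$brain_related & joined$core_central)
  nb <- sum(joined$brain_related & !joined$core_central)
  cn <- sum(!joined$brain_related & joined$core_central)
  nn <- sum(!joined$brain_related & !joined$core_central)
  ef <- if (cn == 0) {
    warn("No non-brain tissue with central core genes; enrichment factor is undefined.")
    NA_real_
  } else {
    (cb / (cb + nb)) / (cn / (cn + nn))
  }
  tab <- matrix(c(cb, nb, cn, nn), nrow = 2,
                dimnames = list(c("central", "noncentral"), c("brain", "nonbrain")))
  chi2 <- chi_squared_stat(tab)
  tibble(
    central_brain = cb, noncentral_brain = nb,
    central_nonbrain = cn, noncentral_nonbrain = nn,
    enrichment_factor = ef,
    chi2 = chi2,
    p_value = pchisq(chi2, df = 1, lower.tail = FALSE)
  )
}
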