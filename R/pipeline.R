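#' Run the end-to-end core-periphery study from a declarative config
#'
#' Sequences the whole per-tissue analysis — node strengths and core
#' centrality, full-network and core-subgraph community detection,
#' reordered contingency table with chi-squared and Cramer's V,
#' strength-weighted sampling control, optional annotation enrichment with
#' regrouping control, and optional phenotype stratification — writing all
#' artifacts under `output_dir` plus a machine-readable `summary.json` and a
#' human-readable `run.log`. Identical config and seed give an identical
#' bundle.
#'
#' The config is a YAML file or an equivalent named list:
#' \preformatted{
#' seed: 42
#' output_dir: out/
#' thresholds: {alpha: 0.05, p_cut: 0.001, q_cut: 0.05, min_cluster_size: 10}
#' replicates: 10
#' tissues:
#'   - name: relevant
#'     simulate: {n_nodes: 800, n_communities: 4, core_size: 80, concordance: 1.0}
#'   - name: other
#'     network: edges.tsv      # or real input files instead of simulate:
#'     core_genes: core.txt    # one gene id per line
#' annotations: simulate       # or a GMT path, or omit to skip enrichment
#' subjects: simulate          # or a phenotype table path, or omit
#' }
#'
#' @param config Path to a YAML config file, or a named list.
#' @return Invisibly, the summary list (also written as JSON).
#' @export
run_study <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  cfg <- validate_config(cfg)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$output_dir, "run.log")
  log_lines <- character(0)
  log_msg <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  th <- cfg$thresholds
  summary <- list(seed = cfg$seed, tissues = list())
  for (t_idx in seq_along(cfg$tissues)) {
    ts <- cfg$tissues[[t_idx]]
    name <- ts$name
    tdir <- file.path(cfg$output_dir, name)
    dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
    stage_seed <- function(offset) cfg$seed + 100L * t_idx + offset
    res <- withCallingHandlers(
      run_tissue(ts, tdir, th, cfg, stage_seed, log_msg),
      error = function(e) {
        abort(sprintf("Stage failure in tissue '%s': %s", name, conditionMessage(e)),
              parent = e)
      }
    )
    summary$tissues[[name]] <- res
  }
  if (length(summary$tissues) > 0) {
    vs <- vapply(summary$tissues, function(x) x$concordance$v, numeric(1))
    summary$highest_v_tissue <- names(which.max(vs))
  }
  jsonlite::write_json(summary, file.path(cfg$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_lines(log_lines, log_path)
  invisible(summary)
}

validate_config <- function(cfg) {
  if (is.null(cfg$output_dir)) abort("Config must name an output_dir.")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  defaults <- list(alpha = 0.05, p_cut = 0.001, q_cut = 0.05, min_cluster_size = 10L)
  cfg$thresholds <- utils::modifyList(defaults, cfg$thresholds %||% list())
  for (key in c("alpha", "p_cut", "q_cut")) {
    v <- cfg$thresholds[[key]]
    if (v <= 0 || v >= 1) abort(sprintf("Threshold '%s' must lie in (0, 1).", key))
  }
  cfg$replicates <- as.integer(cfg$replicates %||% 10L)
  if (is.null(cfg$tissues) || length(cfg$tissues) == 0) {
    abort("Config must list at least one tissue.")
  }
  for (ts in cfg$tissues) {
    if (is.null(ts$name)) abort("Every tissue entry needs a name.")
    if (is.null(ts$simulate)) {
      for (key in c("network", "core_genes")) {
        if (is.null(ts[[key]])) {
          abort(sprintf("Tissue '%s': provide either simulate: or %s:.", ts$name, key))
        }
        if (!file.exists(ts[[key]])) {
          abort(sprintf("Tissue '%s': input file '%s' does not exist.", ts$name, ts[[key]]))
        }
      }
    }
  }
  for (key in c("annotations", "subjects")) {
    v <- cfg[[key]]
    if (!is.null(v) && !identical(v, "simulate") && !isTRUE(v) && !file.exists(v)) {
      abort(sprintf("Config input '%s': file '%s' does not exist.", key, v))
    }
  }
  cfg
}

run_tissue <- function(ts, tdir, th, cfg, stage_seed, log_msg) {
  if (!is.null(ts$simulate)) {
    sim_args <- ts$simulate
    sim_args$seed <- stage_seed(1L)
    sim <- do.call(generate_tissue, sim_args)
    network <- sim$network
    core <- sim$core
    write_network(network, file.path(tdir, "network.tsv"))
    readr::write_lines(core, file.path(tdir, "core_genes.txt"))
  } else {
    network <- read_network(ts$network)
    core <- readr::read_lines(ts$core_genes)
    core <- core[nzchar(core)]
  }
  log_msg("[%s] network: %d genes, %d edges; %d core genes.",
          ts$name, length(network_genes(network)), nrow(network), length(core))

  strengths <- node_strength(network)
  readr::write_tsv(strengths, file.path(tdir, "strengths.tsv"))
  centrality <- centrality_test(strengths, core, alpha = th$alpha, tissue = ts$name)
  readr::write_tsv(centrality, file.path(tdir, "centrality.tsv"))
  log_msg("[%s] centrality: p = %.3g, core central = %s.",
          ts$name, centrality$p_value, centrality$core_central)

  full_part <- louvain_communities(network, seed = stage_seed(2L),
                                   n_restarts = cfg$replicates)
  full_part <- suppressMessages(
    filter_small_communities(full_part, min_size = th$min_cluster_size)
  )
  readr::write_tsv(as_tibble(full_part), file.path(tdir, "full_partition.tsv"))

  sub <- suppressMessages(core_subgraph(network, core))
  core_part <- louvain_communities(sub, seed = stage_seed(3L),
                                   n_restarts = cfg$replicates)
  readr::write_tsv(as_tibble(core_part), file.path(tdir, "core_partition.tsv"))
  log_msg("[%s] communities: %d full (Q = %.3f), %d core (Q = %.3f).",
          ts$name, max(full_part$community, na.rm = TRUE),
          attr(full_part, "modularity") %||% NA_real_,
          max(core_part$community), attr(core_part, "modularity"))

  tab <- suppressMessages(reorder_diagonal(cluster_contingency(core_part, full_part)))
  utils::write.table(tab$counts, file.path(tdir, "contingency.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  conc <- cramers_v(tab)
  readr::write_tsv(conc, file.path(tdir, "concordance.tsv"))
  log_msg("[%s] concordance: X^2 = %.3f, V = %.3f (n = %d, %d x %d).",
          ts$name, conc$chi2, conc$v, conc$n, conc$r, conc$k)

  ctrl <- suppressMessages(sample_control(
    network, size = length(network_genes(sub)), full_partition = full_part,
    n_replicates = cfg$replicates, seed = stage_seed(4L)
  ))
  readr::write_tsv(ctrl$replicates, file.path(tdir, "sampling_control.tsv"))
  log_msg("[%s] sampling control: mean V = %.3f (sd %.3f).",
          ts$name, ctrl$mean_v, ctrl$sd_v)

  out <- list(
    n_genes = length(network_genes(network)),
    n_edges = nrow(network),
    n_core_connected = length(network_genes(sub)),
    centrality = as.list(centrality[1, c("p_value", "core_central")]),
    concordance = as.list(conc[1, c("chi2", "v", "n", "k", "r")]),
    sampling_control = list(mean_v = ctrl$mean_v, sd_v = ctrl$sd_v,
                            ci = c(ctrl$ci_lower, ctrl$ci_upper))
  )

  annotations <- resolve_annotations(cfg, core_part, stage_seed)
  if (!is.null(annotations)) {
    cells <- subcluster_genes(core_part, full_part)
    background <- core_part$gene
    records <- lapply(cells, function(genes) {
      enrich_cluster(genes, background, annotations,
                     p_cut = th$p_cut, q_cut = th$q_cut)
    })
    flat <- bind_rows(lapply(names(records), function(cell) {
      r <- records[[cell]]
      if (nrow(r) == 0) return(NULL)
      r$cell <- cell
      r[, c("cell", "term_id", "term_name", "N", "B", "n", "b", "fold", "p",
            "q", "significant")]
    }))
    readr::write_tsv(flat, file.path(tdir, "enrichment.tsv"))
    summaries <- summarize_cells(cells, records)
    readr::write_tsv(summaries, file.path(tdir, "cell_summaries.tsv"))
    ctrl_rg <- regroup_control(core_part, annotations,
                               n_replicates = cfg$replicates,
                               seed = stage_seed(5L),
                               p_cut = th$p_cut, q_cut = th$q_cut)
    readr::write_tsv(ctrl_rg$replicates, file.path(tdir, "regroup_control.tsv"))
    out$enrichment <- list(
      n_significant_terms = sum(flat$significant),
      regroup_mean_terms = ctrl_rg$mean_terms,
      regroup_mean_genes = ctrl_rg$mean_genes
    )
    log_msg("[%s] enrichment: %d significant term hits; regroup null mean %.1f terms.",
            ts$name, sum(flat$significant), ctrl_rg$mean_terms)
  }

  subjects <- resolve_subjects(cfg, core_part, full_part, stage_seed)
  if (!is.null(subjects)) {
    cells <- subcluster_genes(core_part, full_part)
    comparisons <- suppressWarnings(compare_all(subjects, cells, alpha = th$alpha))
    readr::write_tsv(comparisons, file.path(tdir, "phenotype_comparisons.tsv"))
    out$phenotype <- list(
      n_comparisons = nrow(comparisons),
      n_significant = sum(comparisons$significant)
    )
    log_msg("[%s] phenotype: %d comparisons, %d significant.",
            ts$name, nrow(comparisons), sum(comparisons$significant))
  }
  out
}

resolve_annotations <- function(cfg, core_part, stage_seed) {
  a <- cfg$annotations
  if (is.null(a)) return(NULL)
  if (identical(a, "simulate") || isTRUE(a)) {
    generate_annotations(core_part, seed = stage_seed(6L))
  } else {
    read_gmt(a)
  }
}

resolve_subjects <- function(cfg, core_part, full_part, stage_seed) {
  s <- cfg$subjects
  if (is.null(s)) return(NULL)
  if (identical(s, "simulate") || isTRUE(s)) {
    cells <- subcluster_genes(core_part, full_part)
    shifts <- setNames(numeric(length(cells)), names(cells))
    if (length(shifts) > 0) shifts[1] <- -8
    generate_phenotypes(cells, n_subjects = 1000L, iq_shift = shifts,
                        seed = stage_seed(7L))
  } else {
    suppressMessages(read_subjects(s))
  }
}

#' Genes of each core-by-full subcluster
#'
#' @param core_partition Partition of the core subgraph.
#' @param full_partition Partition of the full network.
#' @param min_genes Cells with fewer genes are dropped (default 1).
#' @return Named list mapping "CCi:FCj" to the genes in that cell.
#' @export
subcluster_genes <- function(core_partition, full_partition, min_genes = 1L) {
  core <- core_partition[!is.na(core_partition$community), c("gene", "community")]
  full <- full_partition[!is.na(full_partition$community), c("gene", "community")]
  joined <- dplyr::inner_join(core, full, by = "gene", suffix = c("_core", "_full"))
  key <- sprintf("CC%d:FC%d", joined$community_core, joined$community_full)
  cells <- split(joined$gene, key)
  cells[lengths(cells) >= min_genes]
}
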