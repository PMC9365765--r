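#' Canonicalize an edge table into a weighted gene network
#'
#' A weighted gene network is represented as a tibble with columns `gene_a`,
#' `gene_b` and `weight`, one row per unordered gene pair. Canonical form has
#' `gene_a < gene_b` (lexicographic), no self-loops, at most one row per pair
#' and every weight in (0, 1]. Edge weights are posterior-probability-like
#' functional-association scores.
#'
#' Self-loops are dropped (with a message stating how many). Duplicate
#' unordered pairs are collapsed to the maximum weight (with a warning): for
#' "top edge" style networks the strongest reported association is the one to
#' keep.
#'
#' @param edges A data frame whose first three columns are gene, gene, weight
#'   (any names; renamed to `gene_a`, `gene_b`, `weight`).
#' @param validate_weights `"error"` (default) rejects weights outside (0, 1];
#'   `"clamp"` clamps weights > 1 to 1 with a warning. Non-positive weights
#'   are always an error.
#' @return A tibble with columns `gene_a`, `gene_b`, `weight`, sorted by pair.
#' @export
as_gene_network <- function(edges, validate_weights = c("error", "clamp")) {
  validate_weights <- match.arg(validate_weights)
  if (!is.data.frame(edges) || ncol(edges) < 3) {
    abort("`edges` must be a data frame with at least 3 columns (gene_a, gene_b, weight).")
  }
  out <- tibble(
    gene_a = as.character(edges[[1]]),
    gene_b = as.character(edges[[2]]),
    weight = as.numeric(edges[[3]])
  )
  if (anyNA(out$weight)) abort("Non-numeric edge weight encountered.")
  bad <- out$weight <= 0
  if (any(bad)) {
    abort(sprintf("%d edge weight(s) are <= 0; weights must lie in (0, 1].", sum(bad)))
  }
  high <- out$weight > 1
  if (any(high)) {
    if (validate_weights == "clamp") {
      warn(sprintf("%d edge weight(s) > 1 clamped to 1.", sum(high)))
      out$weight[high] <- 1
    } else {
      abort(sprintf("%d edge weight(s) are > 1; weights must lie in (0, 1].", sum(high)))
    }
  }
  loops <- out$gene_a == out$gene_b
  if (any(loops)) {
    inform(sprintf("Dropped %d self-loop(s).", sum(loops)))
    out <- out[!loops, ]
  }
  a <- pmin(out$gene_a, out$gene_b)
  b <- pmax(out$gene_a, out$gene_b)
  out$gene_a <- a
  out$gene_b <- b
  key <- paste(out$gene_a, out$gene_b, sep = "\r")
  if (anyDuplicated(key)) {
    warn(sprintf(
      "Collapsed %d duplicate edge(s); kept the maximum weight per pair.",
      sum(duplicated(key))
    ))
    out <- out |>
      group_by(.data$gene_a, .data$gene_b) |>
      summarise(weight = max(.data$weight), .groups = "drop")
  }
  arrange(out, .data$gene_a, .data$gene_b)
}

#' Genes present in a network
#'
#' @param edges A gene network edge tibble (see [as_gene_network()]).
#' @return Sorted character vector of gene identifiers incident to >= 1 edge.
#' @export
network_genes <- function(edges) {
  sort(unique(c(as.character(edges[[1]]), as.character(edges[[2]]))))
}

#' Read a weighted gene network from an edge-list file
#'
#' Expects whitespace- or tab-delimited lines `gene_a gene_b weight`, the
#' format of tissue-specific "top edges" functional-network downloads. There
#' is no header by default; a header line is detected and skipped when the
#' third field of the first line is non-numeric.
#'
#' @param path Path to the edge-list file.
#' @inheritParams as_gene_network
#' @return A canonical gene network tibble (see [as_gene_network()]).
#' @export
read_network <- function(path, validate_weights = c("error", "clamp")) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("'%s' contains no data lines.", path))
  fields <- strsplit(trimws(lines), "[ \t]+")
  first <- fields[[1]]
  skip_header <- length(first) >= 3 &&
    is.na(suppressWarnings(as.numeric(first[3])))
  line_no <- seq_along(fields)
  if (skip_header) {
    fields <- fields[-1]
    line_no <- line_no[-1]
    if (length(fields) == 0) abort(sprintf("'%s' contains only a header line.", path))
  }
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf(
      "Parse error in '%s' at line %d: expected >= 3 whitespace-delimited fields.",
      path, line_no[which(nf < 3)[1]]
    ))
  }
  w <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3)))
  if (anyNA(w)) {
    abort(sprintf(
      "Parse error in '%s' at line %d: weight is not numeric.",
      path, line_no[which(is.na(w))[1]]
    ))
  }
  as_gene_network(
    tibble(
      gene_a = vapply(fields, `[`, character(1), 1),
      gene_b = vapply(fields, `[`, character(1), 2),
      weight = w
    ),
    validate_weights = validate_weights
  )
}

#' Write a gene network as a headerless tab-separated edge list
#'
#' Weights are written with full double precision so that a write/read
#' round trip reproduces the network bit for bit.
#'
#' @param edges A gene network edge tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(edges, path) {
  edges <- as_gene_network(edges)
  readr::write_lines(
    sprintf("%s\t%s\t%s", edges$gene_a, edges$gene_b,
            formatC(edges$weight, digits = 17, format = "g")),
    path
  )
  invisible(path)
}

#' Read a gene evidence-score table
#'
#' Two delimited columns: gene identifier and a categorical evidence score
#' (for example SFARI gene scores). Gene identifiers must be unique.
#'
#' @param path Path to the two-column file (no header).
#' @return A tibble with columns `gene_id` (character) and `score` (character).
#' @export
read_gene_scores <- function(path) {
  tab <- readr::read_table(path, col_names = c("gene_id", "score"),
                           col_types = readr::cols(.default = readr::col_character()))
  if (anyDuplicated(tab$gene_id)) {
    abort("Gene score table contains duplicated gene identifiers.")
  }
  as_tibble(tab)
}

#' Select candidate core genes by evidence score
#'
#' Returns the genes whose categorical evidence score is *not* in
#' `excluded_scores`. The default excludes scores "5" and "6", the low-evidence
#' and non-validated grades of the SFARI-style scoring scheme, leaving the
#' putative core-gene set.
#'
#' @param scores A gene score tibble (see [read_gene_scores()]).
#' @param excluded_scores Character vector of score categories to drop.
#' @return Character vector of retained gene identifiers.
#' @export
select_core_genes <- function(scores, excluded_scores = c("5", "6")) {
  stopifnot(is.data.frame(scores))
  keep <- !(as.character(scores$score) %in% as.character(excluded_scores))
  out <- as.character(scores$gene_id[keep])
  if (length(out) == 0) warn("No genes remain after score exclusion.")
  out
}

#' Read a symbol-to-numeric identifier map
#'
#' @param path Two-column delimited file (symbol, numeric_id), no header.
#' @return A tibble with columns `symbol` and `numeric_id` (both character).
#' @export
read_identifier_map <- function(path) {
  tab <- readr::read_table(path, col_names = c("symbol", "numeric_id"),
                           col_types = readr::cols(.default = readr::col_character()))
  validate_identifier_map(tab)
}

validate_identifier_map <- function(map) {
  stopifnot(is.data.frame(map), ncol(map) >= 2)
  map <- tibble(symbol = as.character(map[[1]]),
                numeric_id = as.character(map[[2]]))
  if (anyDuplicated(map$symbol)) {
    abort("Identifier map contains duplicated symbols; a symbol must map to at most one id.")
  }
  map
}

#' Translate gene identifiers through a map
#'
#' Missing mappings are reported, never fatal: genes without a map entry are
#' returned separately so the caller can drop or inspect them.
#'
#' @param genes Character vector of source identifiers.
#' @param map An identifier map (see [read_identifier_map()]).
#' @return A list with `mapped` (translated ids) and `unmapped` (source ids
#'   that had no entry).
#' @export
map_identifiers <- function(genes, map) {
  map <- validate_identifier_map(map)
  genes <- as.character(genes)
  idx <- match(genes, map$symbol)
  unmapped <- genes[is.na(idx)]
  if (length(unmapped) > 0) {
    inform(sprintf("%d of %d identifier(s) had no mapping and were reported as unmapped.",
                   length(unmapped), length(genes)))
  }
  list(mapped = map$numeric_id[idx[!is.na(idx)]], unmapped = unmapped)
}

#' Read a tissue label table
#'
#' @param path Two-column delimited file: tissue name, then `TRUE`/`FALSE`
#'   (or `1`/`0`) for whether the tissue is brain-related. No header.
#' @return A tibble with columns `tissue` (character) and `brain_related`
#'   (logical).
#' @export
read_tissue_labels <- function(path) {
  tab <- readr::read_table(path, col_names = c("tissue", "brain_related"),
                           col_types = readr::cols(.default = readr::col_character()))
  if (anyDuplicated(tab$tissue)) abort("Tissue label table has duplicated tissue names.")
  flag <- toupper(tab$brain_related)
  parsed <- flag %in% c("TRUE", "T", "1", "YES")
  bad <- !(flag %in% c("TRUE", "T", "1", "YES", "FALSE", "F", "0", "NO"))
  if (any(bad)) abort("brain_related column must be logical (TRUE/FALSE or 1/0).")
  tibble(tissue = tab$tissue, brain_related = parsed)
}

#' Read annotation gene sets in GMT format
#'
#' One term per line: `term_id<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to the GMT file.
#' @return A tibble with columns `term_id`, `term_name`, `genes` (list column
#'   of character vectors) and `n_genes`.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("GMT parse error at line %d: expected term, description and >= 1 gene.",
                  which(nf < 3)[1]))
  }
  out <- tibble(
    term_id = vapply(fields, `[`, character(1), 1),
    term_name = vapply(fields, `[`, character(1), 2),
    genes = lapply(fields, function(x) unique(x[-(1:2)]))
  )
  if (anyDuplicated(out$term_id)) abort("GMT file contains duplicated term ids.")
  out$n_genes <- lengths(out$genes)
  out
}

#' Write annotation gene sets in GMT format
#'
#' @param annotations Annotation tibble as returned by [read_gmt()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(annotations, path) {
  readr::write_lines(
    vapply(seq_len(nrow(annotations)), function(i) {
      paste(c(annotations$term_id[i], annotations$term_name[i],
              annotations$genes[[i]]), collapse = "\t")
    }, character(1)),
    path
  )
  invisible(path)
}

#' Read a subject phenotype table
#'
#' Tab-separated with header columns `subject_id`, `iq`, `age_of_walking`,
#' `disruptive_genes` (semicolon-separated gene list, possibly empty).
#' Subjects missing either trait are dropped with a message; downstream group
#' comparisons require both traits.
#'
#' @param path Path to the phenotype table.
#' @return A tibble with columns `subject_id`, `iq` (points),
#'   `age_of_walking` (months) and `disruptive_genes` (list column).
#' @export
read_subjects <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    iq = readr::col_double(),
    age_of_walking = readr::col_double(),
    disruptive_genes = readr::col_character()
  ))
  if (anyDuplicated(tab$subject_id)) abort("Subject table has duplicated subject ids.")
  keep <- !is.na(tab$iq) & !is.na(tab$age_of_walking)
  if (any(!keep)) {
    inform(sprintf("Dropped %d subject(s) missing IQ or age-of-walking.", sum(!keep)))
    tab <- tab[keep, ]
  }
  genes <- strsplit(ifelse(is.na(tab$disruptive_genes), "", tab$disruptive_genes), ";",
                    fixed = TRUE)
  tab$disruptive_genes <- lapply(genes, function(x) unique(x[nzchar(x)]))
  tab
}

#' Write a subject phenotype table
#'
#' @param subjects Subject tibble (see [read_subjects()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_subjects <- function(subjects, path) {
  out <- tibble(
    subject_id = subjects$subject_id,
    iq = subjects$iq,
    age_of_walking = subjects$age_of_walking,
    disruptive_genes = vapply(subjects$disruptive_genes, paste, character(1),
                              collapse = ";")
  )
  readr::write_tsv(out, path)
  invisible(path)
}
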