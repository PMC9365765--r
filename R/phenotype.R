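#' Assign subjects to carrier / non-carrier groups for one subcluster
#'
#' A subject is a carrier of a tested subcluster when it has at least one
#' disruptive variant in that subcluster's genes — even if it also carries
#' variants elsewhere (carriers are assigned exclusively to the tested
#' subcluster). Everyone else, including subjects with variants only in
#' other subclusters or no variants at all, is the comparison group. The
#' two groups are disjoint and jointly cover all subjects.
#'
#' @param subjects Subject tibble (see [read_subjects()]).
#' @param genes Character vector: the tested subcluster's genes.
#' @return `subjects` with an added logical `carrier` column.
#' @export
assign_subjects <- function(subjects, genes) {
  genes <- unique(as.character(genes))
  subjects$carrier <- vapply(subjects$disruptive_genes, function(g) {
    any(g %in% genes)
  }, logical(1))
  subjects
}

#' Welch two-sample comparison of a trait between carriers and non-carriers
#'
#' Two-sided Welch (unequal-variance) t-test with Welch-Satterthwaite
#' degrees of freedom and the 95% confidence interval of the mean
#' difference. The reported `difference` is mean(carriers) minus
#' mean(non-carriers), matching the sign of the confidence interval.
#'
#' @param subjects Subject tibble with a logical `carrier` column (see
#'   [assign_subjects()]).
#' @param trait `"iq"` or `"age_of_walking"`.
#' @param group_label Optional label carried into the result row.
#' @return A one-row tibble: `group_label`, `trait`, `n_in`, `n_out`,
#'   `mean_in`, `mean_out`, `difference`, `t_statistic`, `df`, `p_value`,
#'   `ci_lower`, `ci_upper`.
#' @export
welch_compare <- function(subjects, trait = c("iq", "age_of_walking"),
                          group_label = NA_character_) {
  trait <- match.arg(trait)
  x <- subjects[[trait]][subjects$carrier]
  y <- subjects[[trait]][!subjects$carrier]
  if (length(x) < 2 || length(y) < 2) {
    abort("Both carrier and non-carrier groups need at least 2 subjects.")
  }
  if (sd(x) == 0 && sd(y) == 0) {
    abort("Zero variance in both groups; the t statistic is undefined.")
  }
  ht <- t.test(x, y, alternative = "two.sided", var.equal = FALSE)
  tibble(
    group_label = group_label,
    trait = trait,
    n_in = length(x),
    n_out = length(y),
    mean_in = mean(x),
    mean_out = mean(y),
    difference = mean(x) - mean(y),
    t_statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    ci_lower = ht$conf.int[1],
    ci_upper = ht$conf.int[2]
  )
}

#' Compare a trait across all subclusters with FDR correction
#'
#' Runs [welch_compare()] for every subcluster (carriers vs all others),
#' separately per trait, and applies Benjamini-Hochberg correction across
#' the tested subclusters within each trait. Subclusters with fewer than 2
#' carriers are skipped with a warning.
#'
#' @param subjects Subject tibble.
#' @param cell_genes Named list mapping subcluster id to its gene set.
#' @param traits Traits to test (default both).
#' @param n_tests Number of tests to correct for, per trait. Defaults to the
#'   number of comparisons actually run; set explicitly to correct for a
#'   larger planned family.
#' @param alpha Significance cut-off on the q-value (default 0.05).
#' @return A tibble of [welch_compare()] rows with `q_value` and
#'   `significant` columns added.
#' @export
compare_all <- function(subjects, cell_genes,
                        traits = c("iq", "age_of_walking"),
                        n_tests = NULL, alpha = 0.05) {
  out <- purrr::map(traits, function(tr) {
    rows <- purrr::map(names(cell_genes), function(cell) {
      assigned <- assign_subjects(subjects, cell_genes[[cell]])
      if (sum(assigned$carrier) < 2) {
        warn(sprintf("Subcluster '%s': fewer than 2 carriers; comparison skipped.", cell))
        return(NULL)
      }
      welch_compare(assigned, trait = tr, group_label = cell)
    })
    res <- bind_rows(rows)
    if (nrow(res) == 0) return(res)
    m <- max(n_tests %||% nrow(res), nrow(res))
    res$q_value <- p.adjust(res$p_value, method = "BH", n = m)
    res$significant <- res$q_value < alpha
    res
  })
  bind_rows(out)
}
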