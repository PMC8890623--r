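# Two-group Wilcoxon rank-sum comparisons with the pooling rule used for the
# domain-group analysis, and the per-group summary table.

#' Median of a numeric vector
#'
#' Middle order statistic; for even n the arithmetic mean of the two middle
#' values (so a 26-value group with middle pair 1321, 1322 has median 1321.5).
#'
#' @param values non-empty numeric vector (NAs removed).
#' @return the median.
#' @export
cohort_median <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("cannot take the median of zero values")
  stats::median(values)
}

#' Two-sided Wilcoxon rank-sum (Mann-Whitney) comparison
#'
#' Exact enumeration when both groups are tie-free and no larger than
#' \code{exact_max_n}; otherwise the normal approximation with midranks,
#' tie-corrected variance and continuity correction. Symmetric in (a, b).
#'
#' @param a,b numeric vectors (non-empty after NA removal).
#' @param exact_max_n largest group size for the exact test (default 25).
#' @param names labels for the two groups.
#' @return a \code{comparison_result}: list with \code{groups}, \code{n},
#'   \code{medians}, \code{statistic} (Mann-Whitney U of the first group),
#'   \code{p_value}, \code{method} ("exact" or
#'   "normal-approximation-with-tie-correction").
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value  # exact two-sided 0.1
#' @export
wilcoxon_rank_sum <- function(a, b, exact_max_n = 25L,
                              names = c("a", "b")) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- !ties && max(length(a), length(b)) <= exact_max_n
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  structure(list(groups = names,
                 n = c(length(a), length(b)),
                 medians = c(cohort_median(a), cohort_median(b)),
                 statistic = unname(ht$statistic),
                 p_value = min(1, unname(ht$p.value)),
                 method = if (exact) "exact"
                          else "normal-approximation-with-tie-correction"),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum: %s (n=%d, median=%g) vs %s (n=%d, median=%g)\n",
              x$groups[1], x$n[1], x$medians[1],
              x$groups[2], x$n[2], x$medians[2]))
  cat(sprintf("  U = %g, two-sided p = %.4g  [%s]\n",
              x$statistic, x$p_value, x$method))
  invisible(x)
}

# Resolve a pool spec (vector of sample ids) to metric values, dropping and
# counting samples without the metric.
pool_values <- function(profiles, ids, metric) {
  v <- profiles[[metric]][match(ids, profiles$sample_id)]
  n_na <- sum(is.na(v))
  if (n_na) message("compare_pooled: excluded ", n_na,
                    " sample(s) lacking ", metric)
  v[!is.na(v)]
}

#' Compare two pooled sample sets on a per-sample metric
#'
#' Implements the pooling rule used for single rank-sum tests: member-group
#' values are concatenated into one vector per side, then one two-sided
#' Wilcoxon rank-sum test is run.
#'
#' @param profiles sample profiles (with \code{pct_at_g4} attached when that
#'   metric is requested).
#' @param pool_a,pool_b character vectors of sample ids (e.g. from
#'   [combine_groups()] or [select_ran()]).
#' @param metric \code{"total_mutations"} or \code{"pct_at_g4"}.
#' @param names labels for the two pools.
#' @param exact_max_n passed to [wilcoxon_rank_sum()].
#' @return a \code{comparison_result}.
#' @export
compare_pooled <- function(profiles, pool_a, pool_b,
                           metric = c("total_mutations", "pct_at_g4"),
                           names = c("A", "B"), exact_max_n = 25L) {
  metric <- match.arg(metric)
  va <- pool_values(profiles, pool_a, metric)
  vb <- pool_values(profiles, pool_b, metric)
  if (!length(va) || !length(vb))
    stop("empty pool after exclusions (", metric, ")")
  wilcoxon_rank_sum(va, vb, exact_max_n = exact_max_n, names = names)
}

#' Summary table of domain groups, control sets and their comparisons
#'
#' Per group/control set: n, median total mutations, median percent-at-G4;
#' plus one two-sided rank-sum comparison per requested pair. Deterministic
#' given its inputs.
#'
#' @param profiles sample profiles with groups and \code{pct_at_g4} assigned.
#' @param groups named list of sample-id vectors (domain groups, pools).
#' @param controls named list of sample-id vectors (e.g. Ran, Ran_H).
#' @param metrics metrics to compare (default both).
#' @param comparisons list of character pairs naming entries of
#'   \code{c(groups, controls)} to compare; default: every group against
#'   every control.
#' @param holm also report Holm-adjusted p-values (default FALSE, matching
#'   per-comparison reporting).
#' @return list of class \code{fig5_summary} with \code{groups} (one row per
#'   set) and \code{comparisons} (one row per pair x metric) data.frames.
#' @export
summarize_fig5 <- function(profiles, groups, controls = list(),
                           metrics = c("total_mutations", "pct_at_g4"),
                           comparisons = NULL, holm = FALSE) {
  sets <- c(groups, controls)
  if (!length(sets)) stop("no groups to summarize")
  gtab <- data.frame(
    set = names(sets),
    n = vapply(sets, length, 0L),
    median_total_mutations = vapply(sets, function(ids) {
      v <- profiles$total_mutations[match(ids, profiles$sample_id)]
      if (all(is.na(v))) NA_real_ else cohort_median(v)
    }, 0),
    median_pct_at_g4 = vapply(sets, function(ids) {
      v <- profiles$pct_at_g4[match(ids, profiles$sample_id)]
      if (all(is.na(v))) NA_real_ else cohort_median(v)
    }, 0),
    row.names = NULL, stringsAsFactors = FALSE)

  if (is.null(comparisons))
    comparisons <- unlist(lapply(names(groups), function(g)
      lapply(names(controls), function(ct) c(g, ct))), recursive = FALSE)

  rows <- list()
  for (pair in comparisons) {
    for (metric in metrics) {
      nonempty <- length(sets[[pair[1]]]) && length(sets[[pair[2]]])
      if (!nonempty) next
      cr <- compare_pooled(profiles, sets[[pair[1]]], sets[[pair[2]]],
                           metric = metric, names = pair)
      rows[[length(rows) + 1L]] <- data.frame(
        group_a = pair[1], group_b = pair[2], metric = metric,
        n_a = cr$n[1], n_b = cr$n[2],
        median_a = cr$medians[1], median_b = cr$medians[2],
        statistic = cr$statistic, p_value = cr$p_value, method = cr$method,
        stringsAsFactors = FALSE)
    }
  }
  ctab <- if (length(rows)) do.call(rbind, rows)
          else data.frame(group_a = character(), group_b = character(),
                          metric = character(), n_a = integer(),
                          n_b = integer(), median_a = double(),
                          median_b = double(), statistic = double(),
                          p_value = double(), method = character())
  if (holm && nrow(ctab)) ctab$p_holm <- stats::p.adjust(ctab$p_value, "holm")
  structure(list(groups = gtab, comparisons = ctab), class = "fig5_summary")
}

#' @export
print.fig5_summary <- function(x, ...) {
  cat("Group summary:\n")
  print(x$groups, row.names = FALSE)
  if (nrow(x$comparisons)) {
    cat("\nComparisons (two-sided Wilcoxon rank-sum):\n")
    print(x$comparisons, row.names = FALSE, digits = 4)
  }
  invisible(x)
}
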