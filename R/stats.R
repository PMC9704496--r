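#' Normality-routed two-group test
#'
#' Tests each group for normality with Shapiro-Wilk at `alpha_normality`;
#' if both groups pass, a two-sample Student t-test (equal variances) is
#' used, otherwise the Wilcoxon rank-sum test. P-values are two-sided.
#' A group with zero variance cannot pass the normality gate and routes to
#' the rank-sum test; two identical constant groups are a degenerate input
#' and are reported with `test_used = "degenerate"` and `p_raw = NA`.
#'
#' @param values_a,values_b numeric vectors, each of length >= 3.
#' @param alpha_normality significance level of the Shapiro-Wilk gate
#'   (default 0.05).
#' @param labels the two group labels (for reporting).
#' @param metric metric name (for reporting).
#' @param welch use Welch's unequal-variance t-test instead of Student's on
#'   the normal route.
#' @return a `group_comparison`: list with `metric`, `groups`, `n`, `mean`,
#'   `median`, `test_used` (`"t_test"`, `"wilcoxon_rank_sum"` or
#'   `"degenerate"`), `p_raw`, `p_adjusted` (equal to `p_raw` here;
#'   adjusted by callers testing several hypotheses), `m_comparisons`.
#' @export
route_and_test <- function(values_a, values_b, alpha_normality = 0.05,
                           labels = c("A", "B"), metric = NA_character_,
                           welch = FALSE) {
  a <- as.numeric(values_a); b <- as.numeric(values_b)
  if (length(a) < 3L || length(b) < 3L)
    stop("each group needs >= 3 values to test normality; ",
         "choose a test directly for smaller groups", call. = FALSE)
  if (anyNA(a) || anyNA(b)) stop("NA values in a group", call. = FALSE)

  const_a <- stats::sd(a) == 0
  const_b <- stats::sd(b) == 0
  if (const_a && const_b && a[1L] == b[1L]) {
    test_used <- "degenerate"
    p <- NA_real_
  } else {
    normal <- function(x, const) !const &&
      stats::shapiro.test(x)$p.value > alpha_normality
    if (normal(a, const_a) && normal(b, const_b)) {
      test_used <- "t_test"
      p <- stats::t.test(a, b, var.equal = !welch,
                         alternative = "two.sided")$p.value
    } else {
      test_used <- "wilcoxon_rank_sum"
      p <- stats::wilcox.test(a, b, exact = FALSE,
                              alternative = "two.sided")$p.value
    }
  }
  structure(list(
    metric = metric,
    groups = labels,
    n = c(length(a), length(b)),
    mean = c(mean(a), mean(b)),
    median = c(stats::median(a), stats::median(b)),
    test_used = test_used,
    p_raw = p,
    p_adjusted = p,
    m_comparisons = 1L
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> %s: %s (n=%d, mean %.6g) vs %s (n=%d, mean %.6g)\n  %s, p = %.4g (adjusted %.4g over %d comparisons)\n",
    x$metric %||% "?", x$groups[1L], x$n[1L], x$mean[1L],
    x$groups[2L], x$n[2L], x$mean[2L],
    x$test_used, x$p_raw, x$p_adjusted, x$m_comparisons))
  invisible(x)
}

#' Bonferroni correction
#'
#' Maps each p-value to `min(1, p * m)` where `m = length(p_values)`
#' (delegates to [stats::p.adjust]).
#'
#' @param p_values numeric vector of p-values in \[0, 1\] (`NA` allowed and
#'   propagated).
#' @return adjusted p-values, same length.
#' @export
bonferroni <- function(p_values) {
  p <- as.numeric(p_values)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "bonferroni")
}

# Registry of scalar per-sample metrics usable in group comparisons.
sample_metric <- function(table, metric, percent = 10,
                          entropy_normalization = FALSE) {
  switch(metric,
    read_count = sum(table$count),
    clonotype_count = nrow(table),
    mean_freq = basic_summary(table)$mean_freq,
    geo_mean_freq = basic_summary(table)$geo_mean_freq,
    mean_cdr3nt_len = basic_summary(table)$mean_cdr3nt_len,
    convergence = convergence(table),
    pielou_clonality = pielou_clonality(table),
    clonal_proportion = clonal_proportion(table, percent),
    shannon_wiener = shannon_wiener(table),
    normalized_shannon_wiener =
      normalized_shannon_wiener(table, entropy_normalization),
    inv_simpson = simpson_family(table)$inv_simpson,
    gini_simpson = simpson_family(table)$gini_simpson,
    d50 = d50(table),
    chao1 = unname(chao1(table)["estimate"]),
    gini_coefficient = gini_coefficient(table),
    stop("unknown metric: ", metric, call. = FALSE)
  )
}

SCALAR_METRICS <- c("read_count", "clonotype_count", "mean_freq",
                    "geo_mean_freq", "mean_cdr3nt_len", "convergence",
                    "pielou_clonality", "clonal_proportion", "shannon_wiener",
                    "normalized_shannon_wiener", "inv_simpson",
                    "gini_simpson", "d50", "chao1", "gini_coefficient")

USAGE_METRICS <- c("v_usage", "d_usage", "j_usage")

comparison_row <- function(cmp) {
  data.frame(metric = cmp$metric, group_a = cmp$groups[1L],
             group_b = cmp$groups[2L], n_a = cmp$n[1L], n_b = cmp$n[2L],
             mean_a = cmp$mean[1L], mean_b = cmp$mean[2L],
             median_a = cmp$median[1L], median_b = cmp$median[2L],
             test_used = cmp$test_used, p_raw = cmp$p_raw,
             p_adjusted = cmp$p_adjusted, m_comparisons = cmp$m_comparisons,
             stringsAsFactors = FALSE)
}

#' Compare per-sample metrics between two metadata groups
#'
#' Computes the requested per-sample metric(s) for every sample, splits the
#' samples by a two-level metadata feature, runs the normality-routed test
#' ([route_and_test]) per metric, and Bonferroni-adjusts across the metrics
#' tested in this call. The usage metrics `"v_usage"`, `"d_usage"` and
#' `"j_usage"` expand to one test per segment label (on the per-sample usage
#' fractions from [cohort_usage_table]), with Bonferroni correction over the
#' number of labels.
#'
#' @param cohort a `cohort` with metadata.
#' @param metric character vector of scalar metric names (see Details), or a
#'   single usage metric (`"v_usage"`, `"d_usage"`, `"j_usage"`).
#' @param feature metadata column with exactly 2 levels.
#' @param alpha_normality Shapiro-Wilk gate level.
#' @param percent percentage for `clonal_proportion`.
#' @param weighted frequency-weighted usage (usage metrics only).
#' @param collapse_alleles gene-level usage aggregation (usage metrics only).
#' @param welch use Welch's t-test on the normal route.
#' @details Scalar metrics: `read_count`, `clonotype_count`, `mean_freq`,
#'   `geo_mean_freq`, `mean_cdr3nt_len`, `convergence`, `pielou_clonality`,
#'   `clonal_proportion`, `shannon_wiener`, `normalized_shannon_wiener`,
#'   `inv_simpson`, `gini_simpson`, `d50`, `chao1`, `gini_coefficient`.
#' @return data frame, one row per test: metric, group labels, per-group n,
#'   mean and median, `test_used`, `p_raw`, `p_adjusted`, `m_comparisons`.
#' @export
compare_metric_by_feature <- function(cohort, metric, feature,
                                      alpha_normality = 0.05, percent = 10,
                                      weighted = TRUE,
                                      collapse_alleles = FALSE,
                                      welch = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  md <- cohort$metadata
  if (is.null(md)) stop("cohort has no metadata", call. = FALSE)
  if (is.null(md[[feature]]))
    stop("no such metadata feature: ", feature, call. = FALSE)
  ids <- cohort_samples(cohort)
  lev <- md[[feature]][match(ids, md$sample)]
  levels2 <- sort(unique(as.character(lev)), method = "radix")
  if (length(levels2) != 2L)
    stop(sprintf("feature '%s' must have exactly 2 levels, found %d",
                 feature, length(levels2)), call. = FALSE)
  in_a <- lev == levels2[1L]

  if (length(metric) == 1L && metric %in% USAGE_METRICS) {
    segment <- substr(metric, 1L, 1L)
    um <- cohort_usage_table(cohort, segment, weighted = weighted,
                             collapse_alleles = collapse_alleles)
    genes <- colnames(um)
    rows <- lapply(genes, function(g)
      comparison_row(route_and_test(um[in_a, g], um[!in_a, g],
                                    alpha_normality, labels = levels2,
                                    metric = paste0(metric, ":", g),
                                    welch = welch)))
    out <- do.call(rbind, rows)
    out$m_comparisons <- length(genes)
    out$p_adjusted <- bonferroni_over(out$p_raw, length(genes))
    return(out)
  }

  bad <- setdiff(metric, SCALAR_METRICS)
  if (length(bad))
    stop("unknown metric(s): ", paste(bad, collapse = ", "), call. = FALSE)
  tables <- cohort_split(cohort)
  rows <- lapply(metric, function(mname) {
    vals <- vapply(tables, sample_metric, numeric(1), metric = mname,
                   percent = percent)
    comparison_row(route_and_test(vals[in_a], vals[!in_a], alpha_normality,
                                  labels = levels2, metric = mname,
                                  welch = welch))
  })
  out <- do.call(rbind, rows)
  out$m_comparisons <- length(metric)
  out$p_adjusted <- bonferroni_over(out$p_raw, length(metric))
  out
}

# min(1, p*m) with an explicit m (the number of simultaneous tests), keeping
# NA degenerate entries NA.
bonferroni_over <- function(p, m) pmin(1, p * m)
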