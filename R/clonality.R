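#' Most or least frequent clonotypes
#'
#' Returns the `k` most (or least) frequent clonotypes, sorted by frequency
#' (descending for `"most"`, ascending for `"least"`); ties are broken
#' lexicographically by `cdr3nt`.
#'
#' @param table a [repertoire_table].
#' @param k number of clonotypes, `1 <= k <= nrow(table)`.
#' @param which `"most"` or `"least"`.
#' @return a [repertoire_table] of `k` rows in the requested order.
#' @export
extreme_clonotypes <- function(table, k = 1L, which = c("most", "least")) {
  check_table(table)
  which <- match.arg(which)
  if (k < 1L || k > nrow(table))
    stop(sprintf("k must be in 1..%d, got %s", nrow(table), k), call. = FALSE)
  o <- if (which == "most") order_radix(-table$freq, table$cdr3nt)
       else order_radix(table$freq, table$cdr3nt)
  out <- table[o[seq_len(k)], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Clonality (1 - Pielou evenness)
#'
#' `1 + sum(p_i * ln p_i) / ln(n)`, i.e. one minus the Shannon entropy
#' normalized by its maximum. 0 for a perfectly even repertoire, approaching
#' 1 as reads concentrate in few clonotypes. A single-clonotype repertoire
#' (where `ln n = 0`) is defined as maximally clonal, 1.
#'
#' @param table a [repertoire_table] with frequencies > 0.
#' @return a real in \[0, 1\].
#' @export
pielou_clonality <- function(table) {
  check_table(table, need_freq = TRUE)
  n <- nrow(table)
  if (n == 1L) return(1)
  p <- table$freq
  1 + sum(p * log(p)) / log(n)
}

#' Clonal proportion
#'
#' Smallest number of top clonotypes (by descending frequency) whose
#' cumulative frequency reaches `percent`% of the repertoire.
#'
#' @param table a [repertoire_table].
#' @param percent target percentage in (0, 100].
#' @return an integer count of clonotypes.
#' @export
clonal_proportion <- function(table, percent = 10) {
  check_table(table)
  if (!is.numeric(percent) || length(percent) != 1L ||
      percent <= 0 || percent > 100)
    stop("percent must be in (0, 100]", call. = FALSE)
  o <- order_radix(-table$freq, table$cdr3nt)
  cum <- cumsum(table$freq[o]) / sum(table$freq)
  as.integer(which(cum >= percent / 100 - 1e-12)[1L])
}

#' Abundance band definitions
#'
#' Bands are half-open intervals `(lower, upper]` on clonotype frequency;
#' together they must be contiguous and cover (0, 1]. The defaults follow the
#' usual clonal-expansion categories: rare (0, 1e-5], small (1e-5, 1e-4],
#' medium (1e-4, 1e-3], large (1e-3, 0.01], hyperexpanded (0.01, 1].
#'
#' @param labels band names.
#' @param lower exclusive lower bounds.
#' @param upper inclusive upper bounds.
#' @return an `abundance_bands` data frame.
#' @export
abundance_bands <- function(labels, lower, upper) {
  if (length(labels) != length(lower) || length(lower) != length(upper))
    stop("labels, lower and upper must have equal length", call. = FALSE)
  o <- order(lower)
  labels <- labels[o]; lower <- lower[o]; upper <- upper[o]
  ok <- length(labels) >= 1L && lower[1L] == 0 &&
    upper[length(upper)] == 1 && all(lower < upper) &&
    all(lower[-1L] == upper[-length(upper)])
  if (!ok)
    stop("invalid bands: intervals (lower, upper] must be contiguous and cover (0, 1]",
         call. = FALSE)
  structure(data.frame(label = labels, lower = lower, upper = upper,
                       stringsAsFactors = FALSE),
            class = c("abundance_bands", "data.frame"))
}

#' @rdname abundance_bands
#' @export
default_abundance_bands <- function() {
  abundance_bands(
    labels = c("rare", "small", "medium", "large", "hyperexpanded"),
    lower = c(0, 1e-5, 1e-4, 1e-3, 1e-2),
    upper = c(1e-5, 1e-4, 1e-3, 1e-2, 1)
  )
}

#' Abundance-band decomposition
#'
#' Assigns every clonotype to exactly one frequency band (`freq` in
#' `(lower, upper]`) and returns the aggregate frequency per band. Values sum
#' to 1 (bands with no clonotypes report 0).
#'
#' @param table a [repertoire_table].
#' @param bands an [abundance_bands] object.
#' @return named numeric vector, one value per band, ordered from the
#'   highest-frequency band down.
#' @export
abundance_decomposition <- function(table, bands = default_abundance_bands()) {
  check_table(table)
  if (!inherits(bands, "abundance_bands"))
    stop("bands must be an abundance_bands object", call. = FALSE)
  breaks <- c(bands$lower[1L], bands$upper)
  bin <- cut(table$freq, breaks = breaks, labels = bands$label, right = TRUE)
  if (anyNA(bin))
    stop("frequencies outside (0, 1] cannot be banded", call. = FALSE)
  agg <- tapply(table$freq, bin, sum, default = 0)
  out <- as.numeric(agg)[match(rev(bands$label), names(agg))]
  names(out) <- rev(bands$label)
  out
}
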