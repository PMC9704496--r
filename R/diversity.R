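#' Shannon-Wiener diversity index
#'
#' `exp(-sum(p_i * ln p_i))` — the exponential of the Shannon entropy (the
#' Hill number of order 1), ranging from 1 (single clonotype) to n (uniform
#' repertoire).
#'
#' @param table a [repertoire_table] with frequencies > 0.
#' @return a real in \[1, n\].
#' @export
shannon_wiener <- function(table) {
  check_table(table, need_freq = TRUE)
  p <- table$freq
  exp(-sum(p * log(p)))
}

#' Normalized Shannon-Wiener index
#'
#' As printed in the field's metric tables: `exp(H) / ln(n)` where `H` is the
#' Shannon entropy. With `entropy_normalization = TRUE` the conventional
#' Pielou evenness `H / ln(n)` is returned instead (bounded by 1), for parity
#' with other repertoire tools.
#'
#' @param table a [repertoire_table] with n >= 2 clonotypes.
#' @param entropy_normalization normalize the entropy rather than its
#'   exponential.
#' @return a positive real.
#' @export
normalized_shannon_wiener <- function(table, entropy_normalization = FALSE) {
  check_table(table, need_freq = TRUE)
  n <- nrow(table)
  if (n < 2L)
    stop("normalized Shannon-Wiener is undefined for n < 2 (ln n = 0)",
         call. = FALSE)
  p <- table$freq
  H <- -sum(p * log(p))
  if (entropy_normalization) H / log(n) else exp(H) / log(n)
}

#' Simpson family of indices
#'
#' From the Simpson concentration `D = sum(p_i^2)`: the inverse Simpson index
#' `1/D` (Hill number of order 2) and the Gini-Simpson index `1 - D`.
#'
#' @param table a [repertoire_table].
#' @return named list with `inv_simpson` and `gini_simpson`.
#' @export
simpson_family <- function(table) {
  check_table(table)
  D <- sum(table$freq^2)
  list(inv_simpson = 1 / D, gini_simpson = 1 - D)
}

#' D50 index
#'
#' The percentage of distinct clonotypes needed to account for at least 50%
#' of the reads: clonotypes are ranked by descending count (ties broken
#' lexicographically by `cdr3nt`), `k` is the smallest rank whose cumulative
#' count reaches half the total, and `100 * k / n` is returned.
#'
#' @param table a [repertoire_table].
#' @return a percentage in (0, 100].
#' @export
d50 <- function(table) {
  check_table(table)
  o <- order_radix(-table$count, table$cdr3nt)
  cnt <- table$count[o]
  k <- which(2 * cumsum(as.numeric(cnt)) >= sum(as.numeric(cnt)))[1L]
  100 * k / nrow(table)
}

#' Chao1 richness estimate
#'
#' `S + f1(f1 - 1) / (2(f2 + 1))` where `S` is the observed clonotype count,
#' `f1` the number of singleton clonotypes (count 1) and `f2` the number of
#' doubletons (count 2). The variance is
#' `f2 * (0.5 r^2 + r^3 + 0.25 r^4)` with r = f1/f2; when `f2 = 0` the
#' variance is reported as `NA`.
#'
#' @param table a [repertoire_table] with integer counts.
#' @return named numeric vector `c(estimate=, variance=)`.
#' @export
chao1 <- function(table) {
  check_table(table)
  S <- nrow(table)
  f1 <- sum(table$count == 1L)
  f2 <- sum(table$count == 2L)
  est <- S + f1 * (f1 - 1) / (2 * (f2 + 1))
  var <- if (f2 > 0) {
    r <- f1 / f2
    f2 * (0.5 * r^2 + r^3 + 0.25 * r^4)
  } else NA_real_
  c(estimate = est, variance = var)
}

#' Gini coefficient of clonotype frequencies
#'
#' Ratio of the area between the line of equality and the Lorenz curve to the
#' total area under the line of equality. The Lorenz curve passes through
#' (0, 0) and (i/n, cumulative frequency of the i smallest clonotypes); the
#' area under it is computed by the trapezoid rule, which is exact for this
#' polyline. 0 for a uniform repertoire; always < 1 - 1/n.
#'
#' @param table a [repertoire_table].
#' @return a real in \[0, 1).
#' @export
gini_coefficient <- function(table) {
  check_table(table)
  p <- sort(table$freq) / sum(table$freq)
  n <- length(p)
  L <- cumsum(p)
  area <- sum((c(0, L[-n]) + L) / 2) / n
  (0.5 - area) / 0.5
}

#' All diversity indices of one sample
#'
#' Convenience wrapper returning every diversity index as a named list.
#' `normalized_shannon_wiener` is `NA` for a single-clonotype repertoire,
#' where it is undefined.
#'
#' @inheritParams normalized_shannon_wiener
#' @return named list: `shannon_wiener`, `normalized_shannon_wiener`,
#'   `inv_simpson`, `gini_simpson`, `d50`, `chao1`, `chao1_var`,
#'   `gini_coeff`.
#' @export
diversity_profile <- function(table, entropy_normalization = FALSE) {
  check_table(table, need_freq = TRUE)
  sf <- simpson_family(table)
  ch <- chao1(table)
  list(
    shannon_wiener = shannon_wiener(table),
    normalized_shannon_wiener = if (nrow(table) >= 2L)
      normalized_shannon_wiener(table, entropy_normalization) else NA_real_,
    inv_simpson = sf$inv_simpson,
    gini_simpson = sf$gini_simpson,
    d50 = d50(table),
    chao1 = unname(ch["estimate"]),
    chao1_var = unname(ch["variance"]),
    gini_coeff = gini_coefficient(table)
  )
}
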