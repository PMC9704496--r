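#' Clonotype identity key for overlap comparisons
#'
#' Declares which fields identify "the same clonotype" in two samples. The
#' default `(cdr3nt, v, j)` is the strictest common convention; a laxer
#' `clonotype_key("cdr3aa")` matches on amino-acid sequence alone. At least
#' one sequence field (`cdr3nt` or `cdr3aa`) is required.
#'
#' @param fields ordered subset of `c("cdr3nt", "cdr3aa", "v", "d", "j")`.
#' @return a `clonotype_key` (character vector).
#' @export
clonotype_key <- function(fields = c("cdr3nt", "v", "j")) {
  allowed <- c("cdr3nt", "cdr3aa", "v", "d", "j")
  if (!length(fields) || !all(fields %in% allowed))
    stop("key fields must be a non-empty subset of: ",
         paste(allowed, collapse = ", "), call. = FALSE)
  if (!any(c("cdr3nt", "cdr3aa") %in% fields))
    stop("key must contain at least one sequence field", call. = FALSE)
  structure(unique(fields), class = "clonotype_key")
}

key_strings <- function(table, key) {
  do.call(paste, c(unclass(table)[key], sep = "\r"))
}

#' Hash-join two repertoires on a clonotype key
#'
#' Matches the clonotypes of two samples exactly on the key fields using a
#' single hashed lookup per row (expected O(|a| + |b|); no pairwise scan) and
#' collects the quantities every overlap metric needs: the shared clonotypes
#' with their per-sample counts and whole-sample frequencies, the distinct
#' clonotype counts `d_i`, `d_j`, `d_ij`, and the total read counts `X`, `Y`.
#'
#' @param a,b [repertoire_table]s.
#' @param key a [clonotype_key].
#' @return an `overlap_join`: list with `shared` (data frame `key, x_count,
#'   y_count, x_freq, y_freq`), `d_i`, `d_j`, `d_ij`, `only_x`, `only_y`,
#'   `X`, `Y`; attribute `lookups` records the number of key lookups
#'   performed.
#' @export
overlap_join <- function(a, b, key = clonotype_key()) {
  check_table(a); check_table(b)
  if (!inherits(key, "clonotype_key")) key <- clonotype_key(key)
  ka <- key_strings(a, key)
  kb <- key_strings(b, key)
  m <- match(ka, kb)            # one hashed lookup per row of a
  hit <- !is.na(m)
  join <- structure(list(
    shared = data.frame(key = ka[hit],
                        x_count = a$count[hit], y_count = b$count[m[hit]],
                        x_freq = a$freq[hit], y_freq = b$freq[m[hit]],
                        stringsAsFactors = FALSE),
    d_i = nrow(a), d_j = nrow(b), d_ij = sum(hit),
    only_x = nrow(a) - sum(hit), only_y = nrow(b) - sum(hit),
    X = sum(a$count), Y = sum(b$count)
  ), class = "overlap_join")
  attr(join, "lookups") <- length(ka) + length(kb)
  join
}

#' Set-based overlap metrics
#'
#' From the joined clonotype sets: Jaccard index
#' `d_ij / (d_i + d_j - d_ij)`; overlap coefficient `d_ij / min(d_i, d_j)`;
#' Tversky index `d_ij / (alpha*only_x + beta*only_y + d_ij)` (the default
#' `alpha = beta = 0.5` is the Sorensen-Dice coefficient); relative overlap
#' diversity `d_ij / (d_i * d_j)`.
#'
#' @param join an [overlap_join].
#' @param alpha,beta non-negative Tversky weights, default 0.5.
#' @return named list `jaccard`, `overlap_coeff`, `tversky`,
#'   `rel_overlap_div`.
#' @export
set_metrics <- function(join, alpha = 0.5, beta = 0.5) {
  stopifnot(inherits(join, "overlap_join"))
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0", call. = FALSE)
  if (join$d_i == 0L || join$d_j == 0L)
    stop("degenerate join: a sample has no clonotypes", call. = FALSE)
  list(
    jaccard = join$d_ij / (join$d_i + join$d_j - join$d_ij),
    overlap_coeff = join$d_ij / min(join$d_i, join$d_j),
    tversky = join$d_ij / (alpha * join$only_x + beta * join$only_y + join$d_ij),
    rel_overlap_div = join$d_ij / (join$d_i * join$d_j)
  )
}

#' Frequency-based overlap metrics
#'
#' Over the shared clonotypes of an [overlap_join]:
#' * Morisita-Horn: `2*sum(x*y) / ((sum(x^2)/X^2 + sum(y^2)/Y^2) * X * Y)`
#'   with read counts `x`, `y` on shared clonotypes and whole-sample totals
#'   `X`, `Y` (set `shared_only = FALSE` to run the squared sums over all
#'   clonotypes of each sample instead);
#' * cosine similarity and Pearson correlation of the shared-clonotype
#'   frequency vectors (Pearson is `NA` when fewer than 2 shared clonotypes
#'   or a zero-variance vector makes it undefined);
#' * `F = sqrt(f_ij * f_ji)`, the geometric mean of the total shared
#'   frequency in each sample;
#' * `F2 = sum(sqrt(phi_ik * phi_jk))`, the clonotype-wise sum of geometric
#'   mean frequencies.
#' Frequencies are whole-sample frequencies, not renormalized over the
#' intersection.
#'
#' @param join an [overlap_join].
#' @param shared_only if `FALSE`, the Morisita-Horn denominator sums run over
#'   all clonotypes of each sample rather than the shared set.
#' @param xsq,ysq internal: full-sample sums of squared counts, supplied by
#'   [overlap_metrics] when `shared_only = FALSE`.
#' @return named list `morisita_horn`, `cosine`, `pearson`,
#'   `geo_mean_overlap_freq`, `clonewise_geo_sum`.
#' @export
frequency_metrics <- function(join, shared_only = TRUE, xsq = NULL, ysq = NULL) {
  stopifnot(inherits(join, "overlap_join"))
  s <- join$shared
  if (nrow(s) == 0L)
    return(list(morisita_horn = 0, cosine = 0, pearson = NA_real_,
                geo_mean_overlap_freq = 0, clonewise_geo_sum = 0))
  x <- as.numeric(s$x_count); y <- as.numeric(s$y_count)
  X <- join$X; Y <- join$Y
  if (shared_only) {
    xsq <- sum(x^2); ysq <- sum(y^2)
  } else if (is.null(xsq) || is.null(ysq)) {
    stop("shared_only = FALSE needs full-sample xsq and ysq", call. = FALSE)
  }
  mh <- 2 * sum(x * y) / ((xsq / X^2 + ysq / Y^2) * X * Y)
  fx <- s$x_freq; fy <- s$y_freq
  cosine <- sum(fx * fy) / (sqrt(sum(fx^2)) * sqrt(sum(fy^2)))
  pearson <- if (nrow(s) < 2L || stats::sd(fx) == 0 || stats::sd(fy) == 0)
    NA_real_ else stats::cor(fx, fy)
  list(
    morisita_horn = mh,
    cosine = cosine,
    pearson = pearson,
    geo_mean_overlap_freq = sqrt(sum(fx) * sum(fy)),
    clonewise_geo_sum = sum(sqrt(fx * fy))
  )
}

kl2 <- function(p, m) sum(ifelse(p > 0, p * log2(p / m), 0))

#' Jensen-Shannon divergence of V segment usage
#'
#' JSD (log base 2, so bounded by \[0, 1\]) between the frequency-weighted V
#' usage vectors of two samples, on the union of their V labels with zero
#' fill; `0 * log(0/.)` is taken as 0.
#'
#' @param a,b [repertoire_table]s with at least one resolved V label each.
#' @param collapse_alleles aggregate alleles to gene level first.
#' @return a real in \[0, 1\]: 0 for identical usage, 1 for disjoint support.
#' @export
jsd_v_usage <- function(a, b, collapse_alleles = FALSE) {
  ua <- segment_usage(a, "v", weighted = TRUE,
                      collapse_alleles = collapse_alleles)
  ub <- segment_usage(b, "v", weighted = TRUE,
                      collapse_alleles = collapse_alleles)
  if (identical(names(ua), "unresolved") || identical(names(ub), "unresolved"))
    stop("a sample has only unresolved V labels; JSD of V usage undefined",
         call. = FALSE)
  labels <- sort(unique(c(names(ua), names(ub))), method = "radix")
  P <- structure(numeric(length(labels)), names = labels)
  Q <- P
  P[names(ua)] <- as.numeric(ua)
  Q[names(ub)] <- as.numeric(ub)
  M <- (P + Q) / 2
  0.5 * kl2(P, M) + 0.5 * kl2(Q, M)
}

OVERLAP_METRICS <- c("morisita_horn", "jaccard", "overlap_coeff", "tversky",
                     "cosine", "pearson", "rel_overlap_div",
                     "geo_mean_overlap_freq", "clonewise_geo_sum",
                     "jsd_v_usage")

#' All ten overlap metrics for a sample pair
#'
#' @param a,b [repertoire_table]s.
#' @param key a [clonotype_key] (default `(cdr3nt, v, j)`).
#' @param alpha,beta Tversky weights.
#' @param shared_only see [frequency_metrics].
#' @param collapse_alleles see [jsd_v_usage]. If a sample has only
#'   unresolved V labels, `jsd_v_usage` is reported as `NA` here (the
#'   standalone [jsd_v_usage] raises an error instead).
#' @return named list of the ten metrics: `morisita_horn`, `jaccard`,
#'   `overlap_coeff`, `tversky`, `cosine`, `pearson`, `rel_overlap_div`,
#'   `geo_mean_overlap_freq`, `clonewise_geo_sum`, `jsd_v_usage`.
#' @examples
#' a <- repertoire_table(data.frame(count = c(6, 3, 1),
#'   cdr3nt = c("AAA", "CCC", "GGG"), cdr3aa = c("K", "P", "G")), "A")
#' b <- repertoire_table(data.frame(count = c(1, 3, 6),
#'   cdr3nt = c("AAA", "CCC", "GGG"), cdr3aa = c("K", "P", "G")), "B")
#' overlap_metrics(a, b)$morisita_horn   # 42/92
#' @export
overlap_metrics <- function(a, b, key = clonotype_key(), alpha = 0.5,
                            beta = 0.5, shared_only = TRUE,
                            collapse_alleles = FALSE) {
  join <- overlap_join(a, b, key)
  sm <- set_metrics(join, alpha, beta)
  fm <- frequency_metrics(join, shared_only = shared_only,
                          xsq = if (!shared_only) sum(as.numeric(a$count)^2),
                          ysq = if (!shared_only) sum(as.numeric(b$count)^2))
  jsd <- tryCatch(jsd_v_usage(a, b, collapse_alleles),
                  error = function(e) NA_real_)
  c(fm[c("morisita_horn", "cosine", "pearson")],
    sm,
    fm[c("geo_mean_overlap_freq", "clonewise_geo_sum")],
    list(jsd_v_usage = jsd))[OVERLAP_METRICS]
}

#' Pairwise overlap matrix across a cohort
#'
#' Computes one overlap metric for every unordered sample pair (each pair
#' once) and returns the symmetric sample-by-sample matrix; the diagonal is
#' the metric of a sample against itself.
#'
#' @param cohort a `cohort` of at least 2 samples.
#' @param metric one of `"morisita_horn"`, `"jaccard"`, `"overlap_coeff"`,
#'   `"tversky"`, `"cosine"`, `"pearson"`, `"rel_overlap_div"`,
#'   `"geo_mean_overlap_freq"`, `"clonewise_geo_sum"`, `"jsd_v_usage"`.
#' @inheritParams overlap_metrics
#' @return symmetric numeric matrix with sample ids as dimnames.
#' @export
pairwise_matrix <- function(cohort, metric = "morisita_horn",
                            key = clonotype_key(), alpha = 0.5, beta = 0.5,
                            shared_only = TRUE, collapse_alleles = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  metric <- match.arg(metric, OVERLAP_METRICS)
  tables <- cohort_split(cohort)
  ids <- cohort_samples(cohort)
  if (length(tables) < 2L)
    stop("pairwise_matrix needs at least 2 samples", call. = FALSE)
  n <- length(tables)
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (k in i:n) {
      val <- overlap_metrics(tables[[i]], tables[[k]], key = key,
                             alpha = alpha, beta = beta,
                             shared_only = shared_only,
                             collapse_alleles = collapse_alleles)[[metric]]
      m[i, k] <- val
      m[k, i] <- val
    }
  }
  m
}
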