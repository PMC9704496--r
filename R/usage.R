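seg_labels <- function(table, segment, collapse_alleles) {
  x <- table[[segment]]
  if (collapse_alleles) x <- sub("\\*.*$", "", x)
  x
}

#' V/D/J segment usage of one sample
#'
#' Weighted usage of segment `g` is the total clonotype frequency carried by
#' clonotypes with that segment; unweighted usage is the fraction of distinct
#' clonotypes carrying it. Unresolved labels form their own `"unresolved"`
#' category (they are never dropped or renormalized away). Values sum to 1.
#'
#' @param table a [repertoire_table].
#' @param segment `"v"`, `"d"` or `"j"`.
#' @param weighted weight by clonotype frequency (`TRUE`) or count clonotypes
#'   (`FALSE`).
#' @param collapse_alleles truncate allele-level labels at `*` to aggregate at
#'   the gene level.
#' @return named numeric vector (labels sorted lexicographically), class
#'   `usage_vector`.
#' @export
segment_usage <- function(table, segment = c("v", "d", "j"), weighted = TRUE,
                          collapse_alleles = FALSE) {
  check_table(table)
  segment <- match.arg(segment)
  lab <- seg_labels(table, segment, collapse_alleles)
  vals <- if (weighted) {
    agg <- tapply(table$freq / sum(table$freq), lab, sum)
    structure(as.numeric(agg), names = names(agg))
  } else {
    tab <- table(lab)
    structure(as.numeric(tab) / nrow(table), names = names(tab))
  }
  vals <- vals[order_radix(names(vals))]
  structure(vals, segment = segment, weighted = weighted,
            class = "usage_vector")
}

#' @export
print.usage_vector <- function(x, ...) {
  cat(sprintf("<usage_vector> %s gene, %s\n", toupper(attr(x, "segment")),
              if (attr(x, "weighted")) "frequency-weighted"
              else "clonotype fraction"))
  print(structure(as.numeric(x), names = names(x)), ...)
  invisible(x)
}

#' V-J pairing matrix
#'
#' Aggregate clonotype frequency (or clonotype fraction, if `weighted =
#' FALSE`) per (V, J) label pair. Cells sum to 1; row sums reproduce the V
#' usage vector and column sums the J usage vector.
#'
#' @inheritParams segment_usage
#' @return numeric matrix, rows = V labels, columns = J labels.
#' @export
vj_matrix <- function(table, weighted = TRUE, collapse_alleles = FALSE) {
  check_table(table)
  v <- seg_labels(table, "v", collapse_alleles)
  j <- seg_labels(table, "j", collapse_alleles)
  w <- if (weighted) table$freq / sum(table$freq)
       else rep(1 / nrow(table), nrow(table))
  vl <- sort(unique(v), method = "radix")
  jl <- sort(unique(j), method = "radix")
  m <- matrix(0, length(vl), length(jl), dimnames = list(vl, jl))
  for (i in seq_along(w)) m[v[i], j[i]] <- m[v[i], j[i]] + w[i]
  m
}

#' Cohort-wide usage matrix
#'
#' One row per sample, one column per segment label (the union across
#' samples, absent labels filled with 0). Every row sums to 1.
#'
#' @param cohort a `cohort`.
#' @inheritParams segment_usage
#' @return numeric matrix, rows = samples, columns = segment labels.
#' @export
cohort_usage_table <- function(cohort, segment = c("v", "d", "j"),
                               weighted = TRUE, collapse_alleles = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  segment <- match.arg(segment)
  tables <- cohort_split(cohort)
  if (!length(tables)) abort_empty("cohort")
  usages <- lapply(tables, segment_usage, segment = segment,
                   weighted = weighted, collapse_alleles = collapse_alleles)
  labels <- sort(unique(unlist(lapply(usages, names))), method = "radix")
  m <- matrix(0, length(tables), length(labels),
              dimnames = list(cohort_samples(cohort), labels))
  for (i in seq_along(usages)) m[i, names(usages[[i]])] <- as.numeric(usages[[i]])
  m
}
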