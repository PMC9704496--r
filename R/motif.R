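#' CDR3 amino-acid spectratype
#'
#' Aggregate clonotype frequency per CDR3 amino-acid length; bins sum to 1.
#'
#' @param table a [repertoire_table].
#' @return a `spectratype` (see [spectratype_nt]).
#' @export
aa_spectratype <- function(table) {
  check_table(table)
  new_spectratype(tapply(table$freq, nchar(table$cdr3aa), sum), "aa")
}

#' k-mer motif counts over CDR3 sequences
#'
#' Slides a window of width `k` over every clonotype's CDR3 sequence
#' (amino-acid or nucleotide) and counts each k-mer occurrence, including
#' repeats within one CDR3. Sequences shorter than `k` contribute nothing.
#' Unweighted counting adds 1 per occurrence; weighted counting adds the
#' clonotype's read count.
#'
#' @param table a [repertoire_table].
#' @param alphabet `"aa"` (CDR3 amino acids) or `"nt"` (nucleotides).
#' @param k motif length, >= 1. Default 6, the conventional CDR3 motif width.
#' @param weighted weight occurrences by read count.
#' @return a `motif_counts`: named numeric vector of counts, with attributes
#'   `alphabet`, `k`, `weighted`.
#' @export
kmer_counts <- function(table, alphabet = c("aa", "nt"), k = 6L,
                        weighted = FALSE) {
  check_table(table)
  alphabet <- match.arg(alphabet)
  if (!is.numeric(k) || length(k) != 1L || k < 1)
    stop("k must be a positive integer", call. = FALSE)
  k <- as.integer(k)
  seqs <- if (alphabet == "aa") table$cdr3aa else table$cdr3nt
  nwin <- pmax(0L, nchar(seqs) - k + 1L)
  idx <- rep.int(seq_along(seqs), nwin)
  starts <- sequence(nwin)
  kmers <- substring(seqs[idx], starts, starts + k - 1L)
  w <- if (weighted) as.numeric(table$count)[idx] else rep(1, length(idx))
  counts <- if (length(kmers)) {
    agg <- rowsum(w, kmers)
    structure(as.numeric(agg), names = rownames(agg))
  } else structure(numeric(0), names = character(0))
  counts <- counts[order_radix(names(counts))]
  structure(counts, alphabet = alphabet, k = k, weighted = weighted,
            class = "motif_counts")
}

#' @export
print.motif_counts <- function(x, ...) {
  cat(sprintf("<motif_counts> %d distinct %d-mers (%s, %s)\n", length(x),
              attr(x, "k"), attr(x, "alphabet"),
              if (attr(x, "weighted")) "read-weighted" else "per occurrence"))
  print(utils::head(structure(as.numeric(x), names = names(x))[
    order(-as.numeric(x))], 10L), ...)
  invisible(x)
}

#' Most abundant motifs
#'
#' Top `m` motifs by count; ties are broken lexicographically. If fewer than
#' `m` distinct motifs exist, all are returned.
#'
#' @param counts a `motif_counts` from [kmer_counts].
#' @param m number of motifs to report.
#' @return data frame with columns `motif` and `count`, in rank order.
#' @export
top_motifs <- function(counts, m = 10L) {
  stopifnot(inherits(counts, "motif_counts"))
  if (!is.numeric(m) || length(m) != 1L || m < 1)
    stop("m must be a positive integer", call. = FALSE)
  o <- order_radix(-as.numeric(counts), names(counts))
  o <- o[seq_len(min(m, length(counts)))]
  data.frame(motif = names(counts)[o], count = as.numeric(counts)[o],
             stringsAsFactors = FALSE)
}

#' Cohort-level motif counts
#'
#' Sum of per-sample motif counts across a cohort (each sample's unweighted
#' occurrence counts by default; set `weighted = TRUE` for read-weighted
#' counts).
#'
#' @param cohort a `cohort`.
#' @inheritParams kmer_counts
#' @return a `motif_counts`.
#' @export
cohort_kmer_counts <- function(cohort, alphabet = c("aa", "nt"), k = 6L,
                               weighted = FALSE) {
  stopifnot(inherits(cohort, "cohort"))
  alphabet <- match.arg(alphabet)
  per <- lapply(cohort_split(cohort), kmer_counts, alphabet = alphabet,
                k = k, weighted = weighted)
  all_names <- sort(unique(unlist(lapply(per, names))), method = "radix")
  total <- structure(numeric(length(all_names)), names = all_names)
  for (p in per) total[names(p)] <- total[names(p)] + as.numeric(p)
  structure(total, alphabet = alphabet, k = as.integer(k),
            weighted = weighted, class = "motif_counts")
}
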