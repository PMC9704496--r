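check_table <- function(table, need_freq = FALSE) {
  if (!inherits(table, "repertoire_table"))
    stop("expected a repertoire_table", call. = FALSE)
  if (nrow(table) == 0L) abort_empty("repertoire table")
  if (need_freq && any(table$freq <= 0))
    stop("all clonotype frequencies must be > 0", call. = FALSE)
  invisible(table)
}

#' Basic per-sample repertoire summary
#'
#' Computes the fundamental repertoire metrics: total read count, number of
#' distinct clonotypes n, mean clonotype frequency (sum p_i / n), geometric
#' mean frequency ((prod p_i)^(1/n), evaluated in log space), mean CDR3
#' nucleotide length, and convergence (see [convergence]).
#'
#' @param table a [repertoire_table] with all frequencies > 0.
#' @param weighted_length if `TRUE` (default) the CDR3 length is weighted by
#'   clonotype frequency, `sum(len_i * p_i)`; if `FALSE` the plain mean length
#'   is returned (for parity with tools that report it unweighted).
#' @return named list with `read_count`, `clonotype_count`, `mean_freq`,
#'   `geo_mean_freq`, `mean_cdr3nt_len`, `convergence`.
#' @examples
#' t <- repertoire_table(data.frame(count = c(6, 3, 1),
#'   cdr3nt = c("TGTGCCAGCAGT", "TGCAGTGGG", "TGTAGC"),
#'   cdr3aa = c("CASS", "CSG", "CS")), sample = "S1")
#' basic_summary(t)
#' @export
basic_summary <- function(table, weighted_length = TRUE) {
  check_table(table, need_freq = TRUE)
  p <- table$freq
  n <- nrow(table)
  len <- nchar(table$cdr3nt)
  list(
    read_count = sum(table$count),
    clonotype_count = n,
    mean_freq = sum(p) / n,
    geo_mean_freq = exp(mean(log(p))),
    mean_cdr3nt_len = if (weighted_length) sum(len * p) else mean(len),
    convergence = convergence(table)
  )
}

#' Convergence of a repertoire
#'
#' Mean, over distinct CDR3 amino-acid sequences, of the number of distinct
#' CDR3 nucleotide sequences encoding each one. Equals 1 when every amino-acid
#' sequence has a single nucleotide variant; larger values indicate convergent
#' recombination. V/D/J labels are ignored; only sequences are compared.
#'
#' @param table a [repertoire_table].
#' @return a real >= 1.
#' @export
convergence <- function(table) {
  check_table(table)
  variants <- tapply(table$cdr3nt, table$cdr3aa,
                     function(x) length(unique(x)))
  mean(variants)
}

new_spectratype <- function(freq_by_len, alphabet) {
  lens <- as.integer(names(freq_by_len))
  o <- order(lens)
  structure(as.numeric(freq_by_len)[o], names = lens[o],
            alphabet = alphabet, class = "spectratype")
}

#' CDR3 nucleotide spectratype
#'
#' Aggregate clonotype frequency per CDR3 nucleotide length. Bin values sum
#' to 1.
#'
#' @param table a [repertoire_table].
#' @return a `spectratype`: named numeric vector, names = lengths.
#' @seealso [aa_spectratype] for the amino-acid version.
#' @export
spectratype_nt <- function(table) {
  check_table(table)
  new_spectratype(tapply(table$freq, nchar(table$cdr3nt), sum), "nt")
}

#' @export
print.spectratype <- function(x, ...) {
  cat(sprintf("<spectratype> CDR3 %s lengths %s..%s\n", attr(x, "alphabet"),
              names(x)[1L], names(x)[length(x)]))
  print(unclass(structure(as.numeric(x), names = names(x))), ...)
  invisible(x)
}

#' @export
plot.spectratype <- function(x, ...) {
  graphics::barplot(as.numeric(x), names.arg = names(x),
                    xlab = sprintf("CDR3 %s length", attr(x, "alphabet")),
                    ylab = "aggregate frequency", ...)
  invisible(x)
}
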