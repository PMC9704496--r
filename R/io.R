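#' Build a validated repertoire table
#'
#' Canonicalizes a data frame of clonotypes for one sample: coerces counts to
#' integers and drops zero-count rows, fills missing `v`/`d`/`j` labels with
#' the `"unresolved"` sentinel, upper-cases sequences, collapses duplicate
#' clonotypes (same `cdr3nt`, `v`, `d`, `j`) by summing their counts, and
#' orders rows by descending count then lexicographic `cdr3nt`.
#'
#' Frequencies are recomputed as `count / sum(count)` when the `freq` column
#' is absent or its sum deviates from 1 by more than `1e-3`; otherwise the
#' supplied frequencies are kept verbatim (tolerating upstream rounding).
#' Counts are always authoritative.
#'
#' If only one of `cdr3nt`/`cdr3aa` is present the other is filled from it
#' with a warning, so that every record carries both sequence fields.
#' A warning is also emitted when `cdr3aa` contains `*` or `_` (non-coding
#' CDR3s are expected to have been filtered upstream).
#'
#' @param df data frame with at least `count` and one of `cdr3nt`, `cdr3aa`;
#'   optionally `freq`, `v`, `d`, `j`, `sample`.
#' @param sample sample identifier; overrides any `sample` column.
#' @return a `repertoire_table`: a data frame with columns
#'   `count, freq, cdr3nt, cdr3aa, v, d, j, sample`.
#' @examples
#' repertoire_table(data.frame(count = c(6, 3, 1),
#'                             cdr3nt = c("TGTGCC", "TGCAGT", "TGTAGC"),
#'                             cdr3aa = c("CA", "CS", "CS")), sample = "S1")
#' @export
repertoire_table <- function(df, sample = NULL) {
  if (!is.data.frame(df)) stop("df must be a data.frame", call. = FALSE)
  if (is.null(df$count))
    stop("schema error: missing mandatory column 'count'", call. = FALSE)
  if (is.null(df$cdr3nt) && is.null(df$cdr3aa))
    stop("schema error: need at least one of 'cdr3nt', 'cdr3aa'", call. = FALSE)

  count <- suppressWarnings(as.numeric(df$count))
  if (anyNA(count)) stop("non-numeric values in 'count'", call. = FALSE)
  if (any(count < 0)) stop("negative values in 'count'", call. = FALSE)
  count <- as.integer(round(count))

  freq <- if (!is.null(df$freq)) suppressWarnings(as.numeric(df$freq)) else NULL

  if (is.null(df$cdr3nt)) {
    warning("no 'cdr3nt' column; filling cdr3nt from cdr3aa", call. = FALSE)
    df$cdr3nt <- df$cdr3aa
  }
  if (is.null(df$cdr3aa)) {
    warning("no 'cdr3aa' column; filling cdr3aa from cdr3nt", call. = FALSE)
    df$cdr3aa <- df$cdr3nt
  }
  cdr3nt <- toupper(as.character(df$cdr3nt))
  cdr3aa <- toupper(as.character(df$cdr3aa))

  seg <- function(x) {
    x <- as.character(x %||% rep(NA_character_, length(count)))
    x[is.na(x) | !nzchar(x)] <- "unresolved"
    x
  }
  v <- seg(df$v); d <- seg(df$d); j <- seg(df$j)

  if (is.null(sample)) {
    sample <- unique(as.character(df$sample %||% character()))
    if (length(sample) != 1L)
      stop("sample id missing or not unique; pass `sample=` explicitly",
           call. = FALSE)
  }
  if (!is_string(sample)) stop("sample must be a non-empty string", call. = FALSE)

  keep <- count >= 1L & !is.na(cdr3nt) & nzchar(cdr3nt) &
    !is.na(cdr3aa) & nzchar(cdr3aa)
  if (!any(keep)) abort_empty(sprintf("sample '%s'", sample))
  if (any(count >= 1L & !keep))
    warning("dropping rows with empty CDR3 sequences", call. = FALSE)
  count <- count[keep]; cdr3nt <- cdr3nt[keep]; cdr3aa <- cdr3aa[keep]
  v <- v[keep]; d <- d[keep]; j <- j[keep]
  if (!is.null(freq)) freq <- freq[keep]

  if (any(grepl("[*_]", cdr3aa)))
    warning("cdr3aa contains '*' or '_': input may include non-coding CDR3s",
            call. = FALSE)

  # keep supplied freq only if it already sums to 1 within 1e-3
  keep_freq <- !is.null(freq) && !anyNA(freq) &&
    abs(sum(freq) - 1) <= 1e-3
  if (!keep_freq) freq <- count / sum(count)

  # collapse duplicate clonotypes, summing counts (and freqs)
  key <- paste(cdr3nt, v, d, j, sep = "\r")
  if (anyDuplicated(key)) {
    g <- match(key, key)
    count <- as.integer(rowsum(count, g)[, 1L])
    freq <- rowsum(freq, g)[, 1L]
    first <- !duplicated(key)
    idx <- which(first)
    cdr3nt <- cdr3nt[idx]; cdr3aa <- cdr3aa[idx]
    v <- v[idx]; d <- d[idx]; j <- j[idx]
  }

  o <- order_radix(-count, cdr3nt)
  out <- data.frame(count = count[o], freq = freq[o],
                    cdr3nt = cdr3nt[o], cdr3aa = cdr3aa[o],
                    v = v[o], d = d[o], j = j[o],
                    sample = sample,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("repertoire_table", "data.frame")
  out
}

#' @export
print.repertoire_table <- function(x, ...) {
  cat(sprintf("<repertoire_table> sample %s: %d clonotypes, %d reads\n",
              x$sample[1L], nrow(x), sum(x$count)))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

infer_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  switch(tolower(tools::file_ext(path)), csv = ",", tsv = "\t", txt = "\t",
         "\t")
}

#' Read one clonotype table
#'
#' Reads a TSV/CSV clonotype table in a given column dialect and returns a
#' validated [repertoire_table]. The delimiter is inferred from the file
#' extension (`.csv` comma, otherwise tab) unless given explicitly.
#'
#' @param path path to the file.
#' @param dialect a [dialect_spec] or its name (`"canonical"`, `"mixcr"`,
#'   `"immunoseq"`).
#' @param sample sample identifier; defaults to a `sample` column if present,
#'   else the file name without extension.
#' @param delim field delimiter; overrides extension-based inference.
#' @return a [repertoire_table].
#' @export
read_clonotype_table <- function(path, dialect = "canonical", sample = NULL,
                                 delim = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  if (is.character(dialect)) dialect <- dialect_spec(dialect)
  raw <- utils::read.table(path, header = TRUE, sep = infer_delim(path, delim),
                           quote = "\"", comment.char = "",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) abort_empty(path)
  df <- apply_dialect(raw, dialect)
  if (is.null(sample) && is.null(df$sample))
    sample <- sub("\\.[^.]*$", "", basename(path))
  repertoire_table(df, sample = sample)
}

#' Read a sample metadata table
#'
#' @param path TSV/CSV file with a mandatory `sample` column; every other
#'   column is a categorical feature.
#' @param delim optional delimiter override.
#' @return a data frame of metadata.
#' @export
read_metadata <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
  md <- utils::read.table(path, header = TRUE, sep = infer_delim(path, delim),
                          quote = "\"", comment.char = "",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (is.null(md$sample))
    stop("schema error: metadata must have a 'sample' column", call. = FALSE)
  md$sample <- as.character(md$sample)
  md
}

#' Merge repertoire tables and metadata into a cohort
#'
#' Stacks per-sample [repertoire_table]s into a long-format cohort and joins
#' per-sample metadata features. Metadata rows for samples absent from the
#' tables are dropped with a warning; samples lacking a metadata row are an
#' error when metadata is supplied.
#'
#' @param tables a list of [repertoire_table]s (or a single one).
#' @param metadata optional data frame with a `sample` column.
#' @return a `cohort`: a list with elements `data` (long-format clonotype
#'   data frame) and `metadata`.
#' @export
merge_cohort <- function(tables, metadata = NULL) {
  if (inherits(tables, "repertoire_table")) tables <- list(tables)
  if (!length(tables)) abort_empty("cohort")
  stopifnot(all(vapply(tables, inherits, TRUE, "repertoire_table")))
  ids <- vapply(tables, function(t) t$sample[1L], character(1))
  if (anyDuplicated(ids))
    stop("duplicate sample id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  data <- do.call(rbind, lapply(tables, as.data.frame))
  rownames(data) <- NULL
  if (!is.null(metadata)) {
    if (is.null(metadata$sample))
      stop("schema error: metadata must have a 'sample' column", call. = FALSE)
    metadata$sample <- as.character(metadata$sample)
    extra <- setdiff(metadata$sample, ids)
    if (length(extra)) {
      warning("dropping metadata rows with no matching sample: ",
              paste(extra, collapse = ", "), call. = FALSE)
      metadata <- metadata[!metadata$sample %in% extra, , drop = FALSE]
    }
    orphan <- setdiff(ids, metadata$sample)
    if (length(orphan))
      stop("samples missing from metadata: ",
           paste(orphan, collapse = ", "), call. = FALSE)
  }
  structure(list(data = data, metadata = metadata), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d samples, %d clonotype rows%s\n",
              length(cohort_samples(x)), nrow(x$data),
              if (is.null(x$metadata)) "" else
                sprintf(", %d metadata features", ncol(x$metadata) - 1L)))
  invisible(x)
}

#' Sample identifiers of a cohort
#' @param cohort a `cohort`.
#' @return character vector of sample ids.
#' @export
cohort_samples <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  unique(cohort$data$sample)
}

#' Extract one sample from a cohort
#' @param cohort a `cohort`.
#' @param sample sample identifier.
#' @return a [repertoire_table].
#' @export
cohort_table <- function(cohort, sample) {
  stopifnot(inherits(cohort, "cohort"))
  rows <- cohort$data[cohort$data$sample == sample, , drop = FALSE]
  if (!nrow(rows)) stop("no such sample in cohort: ", sample, call. = FALSE)
  rownames(rows) <- NULL
  class(rows) <- c("repertoire_table", "data.frame")
  rows
}

# list of repertoire_table, one per sample
cohort_split <- function(cohort) {
  lapply(cohort_samples(cohort), function(s) cohort_table(cohort, s))
}

#' Read a long-format cohort file
#'
#' Reads a clonotype table holding several samples (distinguished by the
#' `sample` column) and an optional metadata file, and returns a `cohort`.
#'
#' @inheritParams read_clonotype_table
#' @param metadata optional path to a metadata TSV/CSV (see [read_metadata]).
#' @return a `cohort`.
#' @export
read_cohort <- function(path, metadata = NULL, dialect = "canonical",
                        delim = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  if (is.character(dialect)) dialect <- dialect_spec(dialect)
  raw <- utils::read.table(path, header = TRUE, sep = infer_delim(path, delim),
                           quote = "\"", comment.char = "",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) abort_empty(path)
  df <- apply_dialect(raw, dialect)
  if (is.null(df$sample))
    stop("schema error: a cohort file needs a 'sample' column", call. = FALSE)
  tables <- lapply(split(df, df$sample), repertoire_table)
  md <- if (!is.null(metadata)) read_metadata(metadata) else NULL
  merge_cohort(unname(tables), md)
}

#' Write a repertoire table or cohort to TSV/CSV
#'
#' Writes the canonical columns. Frequencies are serialized with 17
#' significant digits so that a read/write round trip is bit-identical.
#'
#' @param x a [repertoire_table] or `cohort`.
#' @param path output file path.
#' @param format `"auto"` (from extension), `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, format = c("auto", "tsv", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "csv") "csv" else "tsv"
  df <- if (inherits(x, "cohort")) x$data else as.data.frame(x)
  df <- df[, intersect(c("count", "freq", "cdr3nt", "cdr3aa", "v", "d", "j",
                         "sample"), names(df)), drop = FALSE]
  if (!is.null(df$freq)) df$freq <- sprintf("%.17g", df$freq)
  ok <- tryCatch({
    utils::write.table(df, path, sep = if (format == "csv") "," else "\t",
                       quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("cannot write to ", path, ": ", conditionMessage(ok), call. = FALSE)
  invisible(path)
}
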