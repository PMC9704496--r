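#' Column dialect of a clonotype table
#'
#' A dialect maps the column names found in an upstream tool's output to the
#' canonical clonotype fields `count`, `freq`, `cdr3nt`, `cdr3aa`, `v`, `d`,
#' `j` and `sample`. Three dialects are built in: `"canonical"` (the native
#' schema, with `#count`/`count` and `freq` headers), `"mixcr"`
#' (`cloneCount`, `cloneFraction`, `nSeqCDR3`, `aaSeqCDR3`, `bestVHit`,
#' `bestDHit`, `bestJHit`) and `"immunoseq"` (`templates`, `rearrangement`,
#' `amino_acid`, `v_resolved`, `d_resolved`, `j_resolved`). A `"custom"`
#' dialect takes an explicit `column_map`.
#'
#' @param name one of `"canonical"`, `"mixcr"`, `"immunoseq"`, `"custom"`.
#' @param column_map named character vector mapping source column names to
#'   canonical field names, e.g. `c(cloneCount = "count")`. Required (and only
#'   honoured) for `name = "custom"`. It must cover `count` and at least one
#'   of `cdr3nt`, `cdr3aa`.
#' @return an object of class `dialect_spec`.
#' @examples
#' dialect_spec("mixcr")
#' dialect_spec("custom", c(n = "count", seq = "cdr3nt", aa = "cdr3aa"))
#' @export
dialect_spec <- function(name = c("canonical", "mixcr", "immunoseq", "custom"),
                         column_map = NULL) {
  name <- match.arg(name)
  if (name == "custom") {
    if (is.null(column_map) || is.null(names(column_map)))
      stop("a custom dialect needs a named column_map (source -> canonical)",
           call. = FALSE)
    bad <- setdiff(unname(column_map), CANONICAL_FIELDS)
    if (length(bad))
      stop("unknown canonical field(s) in column_map: ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (!"count" %in% column_map ||
        !any(c("cdr3nt", "cdr3aa") %in% column_map))
      stop("column_map must cover 'count' and one of 'cdr3nt', 'cdr3aa'",
           call. = FALSE)
    map <- column_map
  } else {
    map <- BUILTIN_DIALECTS[[name]]
  }
  structure(list(name = name, column_map = map), class = "dialect_spec")
}

CANONICAL_FIELDS <- c("count", "freq", "cdr3nt", "cdr3aa", "v", "d", "j",
                      "sample")

# source column -> canonical field; several sources may feed one field
BUILTIN_DIALECTS <- list(
  canonical = c(
    "#count" = "count", count = "count",
    freq = "freq", frequency = "freq",
    cdr3nt = "cdr3nt", cdr3aa = "cdr3aa",
    v = "v", d = "d", j = "j", sample = "sample"
  ),
  mixcr = c(
    cloneCount = "count", cloneFraction = "freq",
    nSeqCDR3 = "cdr3nt", aaSeqCDR3 = "cdr3aa",
    bestVHit = "v", bestDHit = "d", bestJHit = "j",
    allVHitsWithScore = "v", allDHitsWithScore = "d", allJHitsWithScore = "j"
  ),
  immunoseq = c(
    templates = "count", productive_frequency = "freq",
    rearrangement = "cdr3nt", amino_acid = "cdr3aa",
    v_resolved = "v", d_resolved = "d", j_resolved = "j",
    sample_name = "sample"
  )
)

#' @export
print.dialect_spec <- function(x, ...) {
  cat("<dialect_spec>", x$name, "\n")
  m <- x$column_map
  cat(paste0("  ", names(m), " -> ", unname(m), collapse = "\n"), "\n")
  invisible(x)
}

# Rename the columns of a raw data.frame to canonical names.  When two source
# columns map to the same field (e.g. bestVHit and allVHitsWithScore) the
# first one present wins.
apply_dialect <- function(df, dialect) {
  stopifnot(inherits(dialect, "dialect_spec"))
  map <- dialect$column_map
  out <- list()
  for (field in CANONICAL_FIELDS) {
    sources <- names(map)[map == field]
    hit <- sources[sources %in% names(df)]
    if (length(hit)) out[[field]] <- df[[hit[1L]]]
  }
  if (is.null(out$count))
    stop(sprintf("schema error: no column for mandatory field 'count' (dialect %s)",
                 dialect$name), call. = FALSE)
  if (is.null(out$cdr3nt) && is.null(out$cdr3aa))
    stop(sprintf("schema error: no column for 'cdr3nt' or 'cdr3aa' (dialect %s)",
                 dialect$name), call. = FALSE)
  as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
}
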