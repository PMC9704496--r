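# Programmatic fixtures shared across the suite.

# Deterministic distinct DNA string for index i (base-4 digits -> ACGT).
fake_nt <- function(i, len = 12L) {
  digits <- integer(len)
  x <- i
  for (k in seq_len(len)) {
    digits[k] <- x %% 4L
    x <- x %/% 4L
  }
  paste(c("A", "C", "G", "T")[digits + 1L], collapse = "")
}

# Quick repertoire with sensible defaults for everything not supplied.
make_table <- function(counts, cdr3nt = NULL, cdr3aa = NULL, v = NULL,
                       d = NULL, j = NULL, sample = "S1", freq = NULL) {
  n <- length(counts)
  df <- data.frame(
    count = counts,
    cdr3nt = cdr3nt %||% vapply(seq_len(n), fake_nt, character(1)),
    cdr3aa = cdr3aa %||% paste0("CASS", LETTERS[(seq_len(n) - 1L) %% 26 + 1L],
                                seq_len(n)),
    v = v %||% paste0("TRBV", (seq_len(n) - 1L) %% 5 + 1L),
    d = d %||% "TRBD1",
    j = j %||% paste0("TRBJ", (seq_len(n) - 1L) %% 3 + 1L),
    stringsAsFactors = FALSE
  )
  if (!is.null(freq)) df$freq <- freq
  repertoire_table(df, sample = sample)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Random small repertoire drawn from a limited sequence pool so that pairs of
# such tables share clonotypes by chance.
random_table <- function(n, sample = "R1", pool = 12L) {
  counts <- sample.int(20L, n, replace = TRUE)
  ids <- sample.int(pool, n)            # distinct clonotype identities
  nts <- vapply(ids, fake_nt, character(1), len = 9L)
  make_table(counts,
             cdr3nt = nts,
             cdr3aa = vapply(ids, function(i)
               paste(AA20[(i * c(3L, 5L, 7L)) %% 20L + 1L], collapse = ""),
               character(1)),
             v = paste0("TRBV", ids %% 4L + 1L),
             d = paste0("TRBD", ids %% 2L + 1L),
             j = paste0("TRBJ", ids %% 3L + 1L),
             sample = sample)
}

uniform_table <- function(n, reads_per_clone = 10L, sample = "U1") {
  make_table(rep(reads_per_clone, n), sample = sample)
}
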