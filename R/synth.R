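# Standard genetic code, codon -> one-letter amino acid ('*' = stop).
GENETIC_CODE_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

SENSE_CODONS <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE != "*"]

#' Translate CDR3 nucleotide sequences
#'
#' Standard-genetic-code translation of in-frame DNA strings (length
#' divisible by 3). Stop codons translate to `*`.
#'
#' @param nt character vector of uppercase DNA strings.
#' @return character vector of amino-acid strings.
#' @export
translate_cdr3 <- function(nt) {
  vapply(nt, function(s) {
    if (nchar(s) %% 3L != 0L)
      stop("sequence length not divisible by 3: ", s, call. = FALSE)
    codons <- substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
    aa <- GENETIC_CODE_TABLE[codons]
    if (anyNA(aa)) stop("non-ACGT codon in: ", s, call. = FALSE)
    paste(aa, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

default_v_alleles <- function() sprintf("TRBV%02d-01*01", 1:20)
default_d_alleles <- function() sprintf("TRBD%02d-01*01", 1:2)
default_j_alleles <- function() sprintf("TRBJ%02d-0%d*01", rep(1:2, c(6, 7)),
                                        c(1:6, 1:7))

#' Specification for synthetic repertoire generation
#'
#' Describes the study conditions a generated repertoire emulates: how many
#' clonotypes, how many reads, the clonal abundance model, CDR3 lengths (in
#' codons) and the V/D/J allele pools.
#'
#' Abundance models (weights over clonotypes ranked 1..n):
#' `"uniform"` (equal), `"geometric"` (`r^(i-1)`, default ratio 0.5),
#' `"power_law"` (`i^-s`, default exponent `s = 1.5` — the heavy-tailed shape
#' typical of expanded repertoires).
#'
#' @param n_clonotypes number of distinct clonotypes per sample.
#' @param total_reads reads per sample (scalar, or one value per sample for
#'   [generate_cohort]); must be >= `n_clonotypes`.
#' @param abundance_model `"uniform"`, `"geometric"` or `"power_law"`.
#' @param model_param ratio `r` (geometric) or exponent `s` (power law).
#' @param cdr3_len_range CDR3 length range in codons (amino acids); default
#'   8 to 20, the span observed in beta-chain repertoires.
#' @param v_alleles,d_alleles,j_alleles label pools sampled uniformly.
#' @param n_samples number of samples for [generate_cohort].
#' @param group_labels optional per-sample labels of a 2-level feature,
#'   recycled to `n_samples`; written to cohort metadata as feature `group`.
#' @param seed master RNG seed.
#' @return a `synth_spec`.
#' @export
synth_spec <- function(n_clonotypes = 100L, total_reads = 10000L,
                       abundance_model = c("power_law", "geometric",
                                           "uniform"),
                       model_param = NULL, cdr3_len_range = c(8L, 20L),
                       v_alleles = default_v_alleles(),
                       d_alleles = default_d_alleles(),
                       j_alleles = default_j_alleles(),
                       n_samples = 1L, group_labels = NULL, seed = 1L) {
  abundance_model <- match.arg(abundance_model)
  if (is.null(model_param))
    model_param <- switch(abundance_model, geometric = 0.5, power_law = 1.5,
                          uniform = NA_real_)
  if (n_clonotypes < 1L) stop("n_clonotypes must be >= 1", call. = FALSE)
  if (any(total_reads < n_clonotypes))
    stop("infeasible spec: total_reads < n_clonotypes", call. = FALSE)
  if (length(cdr3_len_range) != 2L || cdr3_len_range[1L] > cdr3_len_range[2L]
      || cdr3_len_range[1L] < 1L)
    stop("cdr3_len_range must be (min, max) codons with 1 <= min <= max",
         call. = FALSE)
  if (!is.null(group_labels)) {
    group_labels <- rep_len(as.character(group_labels), n_samples)
    if (length(unique(group_labels)) != 2L)
      stop("group_labels must define exactly 2 levels", call. = FALSE)
  }
  structure(list(n_clonotypes = as.integer(n_clonotypes),
                 total_reads = as.integer(total_reads),
                 abundance_model = abundance_model,
                 model_param = model_param,
                 cdr3_len_range = as.integer(cdr3_len_range),
                 v_alleles = v_alleles, d_alleles = d_alleles,
                 j_alleles = j_alleles,
                 n_samples = as.integer(n_samples),
                 group_labels = group_labels,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

abundance_weights <- function(spec) {
  n <- spec$n_clonotypes
  switch(spec$abundance_model,
         uniform = rep(1, n),
         geometric = spec$model_param^(seq_len(n) - 1),
         power_law = seq_len(n)^(-spec$model_param))
}

# Round total * w/sum(w) to integers summing exactly to total (largest
# remainder); zero counts are then topped up from the largest counts so that
# every clonotype keeps count >= 1.
largest_remainder <- function(weights, total) {
  target <- total * weights / sum(weights)
  counts <- floor(target)
  rem <- target - counts
  short <- total - sum(counts)
  if (short > 0) {
    o <- order(-rem, seq_along(rem))   # ties: first index wins
    counts[o[seq_len(short)]] <- counts[o[seq_len(short)]] + 1
  }
  while (any(counts == 0)) {
    z <- which(counts == 0)[1L]
    big <- which.max(counts)
    counts[big] <- counts[big] - 1
    counts[z] <- 1
  }
  as.integer(counts)
}

random_cdr3nt <- function(n, len_range) {
  lens <- sample(seq(len_range[1L], len_range[2L]), n, replace = TRUE)
  vapply(lens, function(L)
    paste(sample(SENSE_CODONS, L, replace = TRUE), collapse = ""),
    character(1))
}

#' Generate one synthetic repertoire
#'
#' Draws clonotype counts from the spec's abundance model (rounded by largest
#' remainder so they sum exactly to `total_reads`, with every clonotype
#' keeping at least one read), builds CDR3 nucleotide sequences codon-wise
#' from the 61 sense codons (so the amino-acid translation never contains a
#' stop), and samples V/D/J labels uniformly from the allele pools. The same
#' seed always yields the same table.
#'
#' @param spec a [synth_spec].
#' @param sample sample identifier.
#' @param seed RNG seed (defaults to the spec's).
#' @param total_reads override of the spec's read total.
#' @return a [repertoire_table] satisfying all canonical invariants.
#' @export
generate_repertoire <- function(spec, sample = "S1", seed = spec$seed,
                                total_reads = spec$total_reads[1L]) {
  stopifnot(inherits(spec, "synth_spec"))
  if (total_reads < spec$n_clonotypes)
    stop("infeasible spec: total_reads < n_clonotypes", call. = FALSE)
  with_seed(seed, {
    n <- spec$n_clonotypes
    counts <- largest_remainder(abundance_weights(spec), total_reads)
    nt <- random_cdr3nt(n, spec$cdr3_len_range)
    v <- sample(spec$v_alleles, n, replace = TRUE)
    d <- sample(spec$d_alleles, n, replace = TRUE)
    j <- sample(spec$j_alleles, n, replace = TRUE)
    # regenerate any colliding (cdr3nt, v, d, j) rows so n is preserved
    for (tries in 1:100) {
      key <- paste(nt, v, d, j, sep = "\r")
      dup <- duplicated(key)
      if (!any(dup)) break
      nt[dup] <- random_cdr3nt(sum(dup), spec$cdr3_len_range)
    }
    repertoire_table(data.frame(count = counts, cdr3nt = nt,
                                cdr3aa = translate_cdr3(nt),
                                v = v, d = d, j = j,
                                stringsAsFactors = FALSE),
                     sample = sample)
  })
}

#' Generate a synthetic cohort
#'
#' Generates `n_samples` repertoires with per-sample seeds derived
#' deterministically from the master seed, attaches metadata (a `group`
#' feature when `group_labels` is set), and merges them into a `cohort`.
#' `total_reads` may be a vector with one entry per sample.
#'
#' @param spec a [synth_spec] with `n_samples >= 1`.
#' @return a `cohort`.
#' @examples
#' sp <- synth_spec(n_clonotypes = 50, total_reads = 2000, n_samples = 4,
#'                  group_labels = c("A", "A", "B", "B"), seed = 7)
#' generate_cohort(sp)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  ns <- spec$n_samples
  if (ns < 1L) stop("n_samples must be >= 1", call. = FALSE)
  reads <- rep_len(spec$total_reads, ns)
  seeds <- with_seed(spec$seed, sample.int(.Machine$integer.max - 1L, ns))
  ids <- sprintf("S%02d", seq_len(ns))
  tables <- lapply(seq_len(ns), function(i)
    generate_repertoire(spec, sample = ids[i], seed = seeds[i],
                        total_reads = reads[i]))
  md <- if (!is.null(spec$group_labels))
    data.frame(sample = ids, group = spec$group_labels,
               stringsAsFactors = FALSE)
  merge_cohort(tables, md)
}
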