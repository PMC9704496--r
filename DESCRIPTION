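Package: repstat
Title: T Cell Receptor Repertoire Metrics, Overlap and Group Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-analysis of T cell receptor sequencing (TCR-Seq) clonotype
    tables. Reads tab- or comma-separated clonotype tables (canonical,
    MiXCR-style or ImmunoSEQ-style column dialects), merges samples and
    metadata into a cohort, and computes six families of repertoire metrics:
    basic summaries (read and clonotype counts, mean and geometric-mean
    clonotype frequency, frequency-weighted CDR3 length, convergence,
    spectratype), clonality (1-Pielou evenness, clonal proportion,
    abundance-band decomposition), diversity (Shannon-Wiener, inverse Simpson,
    Gini-Simpson, D50, Chao1 with variance, Gini coefficient), V/D/J segment
    usage and V-J pairing, ten pairwise repertoire-overlap indices
    (Morisita-Horn, Jaccard, overlap coefficient, Tversky, cosine, Pearson,
    relative overlap diversity, geometric-mean overlap frequencies,
    clonotype-wise geometric sum, Jensen-Shannon divergence of V usage), and
    CDR3 k-mer motif counts. A normality-routed two-group testing engine
    (Shapiro-Wilk gated Student t-test or Wilcoxon rank-sum, with Bonferroni
    correction) compares any per-sample metric between metadata groups.
    Includes a seeded synthetic repertoire generator and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    Biostrings
Config/testthat/edition: 3
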