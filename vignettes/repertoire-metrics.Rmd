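---
title: "Repertoire metrics: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repertoire metrics: models, conventions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repstat)
```

## The data model

A TCR-Seq sample, after upstream read processing, is a *clonotype table*:
one row per unique receptor rearrangement with a read count, a frequency,
CDR3 nucleotide and amino-acid sequences, and V/D/J segment labels.
`repertoire_table()` canonicalizes such a table and enforces the invariants
every downstream metric relies on:

* counts are positive integers; rows with zero counts are dropped;
* duplicate clonotypes — identical `(cdr3nt, v, d, j)` — are collapsed by
  summing counts, so "clonotype count" always means distinct clonotypes;
* frequencies sum to 1. Counts are authoritative: `freq` is recomputed as
  `count / sum(count)` unless the supplied column already sums to 1 within
  `1e-3` (tolerating upstream rounding), in which case it is kept verbatim
  so that files round-trip bit-identically;
* missing V/D/J labels become the literal category `"unresolved"`, which is
  retained in usage vectors as its own category. Renormalizing it away would
  silently distort the usage distribution of the resolved genes;
* rows are ordered by descending count, ties broken lexicographically by
  `cdr3nt` (byte order, locale-independent), so all outputs are
  deterministic.

Non-coding CDR3 filtering is deliberately *not* performed — upstream tools
are expected to have removed out-of-frame rearrangements — but a validation
warning fires when `cdr3aa` contains `*` or `_`.

Column dialects (`dialect_spec()`) map MiXCR-style and ImmunoSEQ-style
headers onto this schema; a custom map absorbs vendor drift. When a dialect
provides only one of the two sequence columns, the other is filled from it
with a warning rather than failing, since only one sequence field is needed
to define clonotype identity.

## Metric conventions worth knowing

**Clonality.** `pielou_clonality()` is `1 + Σ pᵢ ln pᵢ / ln n` (one minus
Pielou evenness). For `n = 1` both entropy and `ln n` are zero; the limit is
taken as 1 (maximally clonal) by convention.

**Normalized Shannon-Wiener.** The printed form of this index in the
repertoire literature is `exp(H)/ln n`, which is not bounded by 1 and is
*increasing* in diversity, unlike the conventional Pielou evenness
`H / ln n`. Both are exposed; the printed form is the default and
`entropy_normalization = TRUE` selects the conventional one. Because the two
forms disagree in scale, no monotonicity claim is attached to the default
beyond its formula.

**D50** ranks clonotypes by descending *count* (frequency ties can be
rounding artifacts; counts are exact), ties again broken by `cdr3nt`, and
reports `100·k/n` for the smallest k reaching half the reads.

**Chao1** uses the classic singleton/doubleton estimator
`S + f₁(f₁−1)/(2(f₂+1))`; its variance
`f₂(0.5r² + r³ + 0.25r⁴)`, `r = f₁/f₂`, is reported as `NA` when `f₂ = 0`
rather than switching to a bias-corrected alternative, keeping the estimator
exactly the published closed form.

**Gini coefficient** integrates the discrete Lorenz polyline through
`(i/n, cumulative frequency)` by the trapezoid rule, which is exact for a
step distribution; hence `G = 0` exactly for uniform repertoires and
`G < 1 − 1/n` always.

**Abundance bands** are half-open intervals `(lower, upper]` so every
frequency belongs to exactly one band even at the printed boundaries
(a clone at exactly 0.01 is "large", not "hyperexpanded"). Band edges are
user-configurable; the defaults are the usual rare/small/medium/large/
hyperexpanded cut-offs at powers of ten.

## Overlap analysis

Two samples are compared after an exact join on a declared *clonotype key*.
The field has no single convention for when two clonotypes are "the same",
so the key is explicit: the default `(cdr3nt, v, j)` is the strictest common
choice, and `clonotype_key("cdr3aa")` gives amino-acid-level matching. The
join hashes each key once (`match()` on pre-built key strings), so cost
grows linearly in the two table sizes — the `lookups` attribute of the join
records this contract and the tests assert it, rather than asserting wall
clock.

Conventions resolved where the printed formulas are ambiguous:

* Morisita-Horn runs all its sums over the *shared* clonotypes while the
  totals X, Y are whole-sample read counts, matching the printed symbol
  definitions; `shared_only = FALSE` switches the squared sums to all
  clonotypes of each sample.
* Cosine and Pearson are computed on the shared-clonotype frequency vectors
  (a union-with-zeros variant would mix in the set-overlap signal that the
  set metrics already carry). Pearson is undefined — `NA` — for fewer than
  two shared clonotypes or zero variance.
* F and F2 use whole-sample frequencies, not frequencies renormalized over
  the intersection.
* The Jensen-Shannon divergence of V usage uses log base 2 and the union of
  V labels with zero fill and `0·log 0 = 0`, preserving the [0, 1] bound
  (identical usage → 0, disjoint support → 1). A sample whose V labels are
  all unresolved has no defined V usage: `jsd_v_usage()` errors, and the
  ten-metric aggregate `overlap_metrics()` reports `NA` for that component
  so the other nine remain available.

## Group statistics

The two-group engine mirrors standard practice in repertoire studies:
Shapiro-Wilk on each group at α = 0.05 (the routing threshold is a
parameter); if both groups pass, a Student (equal-variance) t-test — Welch
behind a flag — otherwise the Wilcoxon rank-sum test, always two-sided.
Shapiro-Wilk was chosen as the normality gate because it is the most
powerful omnibus test at the small per-group sample sizes typical of cohort
comparisons. Groups need at least 3 values (the minimum for Shapiro-Wilk); a
zero-variance group cannot be declared normal and routes to the rank-sum
test; two identical constant groups are degenerate and reported with
`test_used = "degenerate"`, `p = NA`. Bonferroni correction multiplies by
the number of *simultaneous* tests in the call — the metrics requested, or
the gene count for per-gene usage comparisons — not an experiment-wide
count. Under a seeded Gaussian null the routed pipeline's empirical size at
α = 0.05 stays within binomial tolerance of the nominal level (checked over
1000 replicates in the test suite).

## The synthetic generator

`generate_cohort()` emulates the features of clonotype tables the metrics
are sensitive to: heavy-tailed clonal abundances (power-law `i^{-s}`,
default s = 1.5; geometric and uniform alternatives), CDR3 nucleotide
sequences built codon-wise from the 61 sense codons with lengths of 8–20
codons (the span of beta-chain CDR3s), amino-acid sequences that are exact
standard-genetic-code translations, and uniform V/D/J draws from
TRB-like allele pools. Counts are rounded by largest remainder so they sum
*exactly* to the requested read total (zero counts are topped up from the
largest clone), which keeps closed-form checks exact: a uniform repertoire
of n clonotypes has Shannon-Wiener = inverse Simpson = n, Gini = 0 and
clonality = 0 to machine precision.

What it does **not** emulate: V(D)J junctional biology (no insertion/
deletion modeling, no germline segment sequence content), public/shared
clonotypes across samples (independently generated samples overlap only by
chance, i.e. essentially never), UMI or sequencing error structure, and any
V-gene usage bias. Passing tests on this generator therefore validate the
*arithmetic* of the metrics and the pipeline plumbing, not biological
realism of any particular dataset.

Determinism: every generator call derives its RNG stream from an explicit
seed and restores the caller's RNG state afterwards; cohorts derive
per-sample seeds from the master seed, so any subset of samples is
reproducible.

## Problem sizes

The test suite checks every metric against independent brute-force oracles
on 200 random repertoires of up to 8 clonotypes (small enough that literal
loop transcriptions of the formulas are obviously correct), plus
closed-form and property checks on generated tables of tens of clonotypes
and a 1000-replicate null calibration of the statistics engine. The results
script uses a 12-sample cohort of 300 clonotypes per sample. These sizes
were chosen so the whole suite runs in well under a minute while still
exercising ties, duplicates, unresolved labels and degenerate inputs.

## Known limitations

* No rarefaction or subsampling-based diversity smoothing; counts are taken
  at face value (no UMI correction).
* Overlap analysis offers exact matching only — no fuzzy/Hamming-distance
  clonotype matching.
* The statistics engine covers exactly two groups; multi-group omnibus
  tests, FDR procedures and paired designs are out of scope.
* Plotting is minimal (spectratype bar plot); the tabular outputs are meant
  to feed whatever visualization stack the user prefers.
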