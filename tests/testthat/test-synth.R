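test_that("generated repertoires satisfy all canonical invariants", {
  spec <- synth_spec(n_clonotypes = 50, total_reads = 3000, seed = 9)
  r <- generate_repertoire(spec)
  expect_s3_class(r, "repertoire_table")
  expect_equal(nrow(r), 50L)
  expect_equal(sum(r$count), 3000L)
  expect_true(all(r$count >= 1L))
  expect_equal(sum(r$freq), 1, tolerance = 1e-9)
  expect_true(all(nchar(r$cdr3nt) %% 3 == 0))
  expect_true(all(grepl("^[ACGT]+$", r$cdr3nt)))
  expect_false(any(grepl("\\*", r$cdr3aa)))
  expect_false(anyDuplicated(paste(r$cdr3nt, r$v, r$d, r$j)) > 0)
})

test_that("generation is deterministic under a fixed seed", {
  spec <- synth_spec(n_clonotypes = 30, total_reads = 900, seed = 77)
  expect_identical(generate_repertoire(spec), generate_repertoire(spec))
  spec4 <- synth_spec(n_clonotypes = 20, total_reads = 600, n_samples = 3,
                      seed = 78)
  c1 <- generate_cohort(spec4)
  c2 <- generate_cohort(spec4)
  expect_identical(c1$data, c2$data)
})

test_that("abundance models shape counts as specified", {
  u <- generate_repertoire(synth_spec(n_clonotypes = 10, total_reads = 100,
                                      abundance_model = "uniform", seed = 1))
  expect_true(all(u$count == 10L))
  expect_equal(pielou_clonality(u), 0, tolerance = 1e-12)

  # geometric(0.5), n=4, 15 reads: exact weights (8,4,2,1)/15
  g <- generate_repertoire(synth_spec(n_clonotypes = 4, total_reads = 15,
                                      abundance_model = "geometric",
                                      model_param = 0.5, seed = 2))
  expect_setequal(g$count, c(8L, 4L, 2L, 1L))

  pl <- generate_repertoire(synth_spec(n_clonotypes = 100,
                                       total_reads = 10000,
                                       abundance_model = "power_law",
                                       model_param = 1.5, seed = 3))
  expect_gt(max(pl$count) / min(pl$count), 50)   # heavy tail
  expect_error(synth_spec(n_clonotypes = 10, total_reads = 5), "infeasible")
})

test_that("uniform repertoires recover closed-form metric values", {
  for (n in c(4L, 7L, 10L)) {
    u <- generate_repertoire(synth_spec(n_clonotypes = n,
                                        total_reads = n * 20L,
                                        abundance_model = "uniform",
                                        seed = n))
    expect_equal(shannon_wiener(u), n, tolerance = 1e-9)
    expect_equal(simpson_family(u)$inv_simpson, n, tolerance = 1e-9)
    expect_equal(gini_coefficient(u), 0, tolerance = 1e-12)
    expect_equal(d50(u), 100 * ceiling(n / 2) / n, tolerance = 1e-12)
  }
})

test_that("cdr3aa is the standard-genetic-code translation of cdr3nt", {
  r <- generate_repertoire(synth_spec(n_clonotypes = 40, total_reads = 800,
                                      seed = 13))
  expect_identical(r$cdr3aa, translate_cdr3(r$cdr3nt))
  # independent codon-table oracle
  bs <- vapply(r$cdr3nt, function(s)
    as.character(Biostrings::translate(Biostrings::DNAString(s))),
    character(1), USE.NAMES = FALSE)
  expect_identical(r$cdr3aa, bs)
})

test_that("cohorts carry group metadata and per-sample read totals", {
  spec <- synth_spec(n_clonotypes = 25, total_reads = c(500, 500, 1000, 1000),
                     n_samples = 4, group_labels = c("A", "A", "B", "B"),
                     seed = 21)
  co <- generate_cohort(spec)
  expect_equal(table(co$metadata$group)[["A"]], 2L)
  reads <- vapply(cohort_samples(co), function(s)
    sum(cohort_table(co, s)$count), numeric(1))
  expect_equal(unname(reads), c(500, 500, 1000, 1000))
  # doubled totals double the read_count group mean exactly
  in_b <- co$metadata$group == "B"
  expect_equal(mean(reads[in_b]) / mean(reads[!in_b]), 2)
})
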