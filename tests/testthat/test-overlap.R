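abc <- function(ids, counts = rep(1, length(ids)), sample = "S") {
  make_table(counts, cdr3nt = paste0(ids, ids, ids),
             cdr3aa = ids, v = "V1", d = "D1", j = "J1", sample = sample)
}

test_that("overlap join counts shared and exclusive clonotypes", {
  a <- abc(c("A", "B", "C"), sample = "a")
  b <- abc(c("B", "C", "D"), sample = "b")
  jn <- overlap_join(a, b)
  expect_equal(jn$d_ij, 2L)
  expect_equal(jn$only_x, 1L)
  expect_equal(jn$only_y, 1L)
  expect_equal(jn$X, 3L)
  ident <- overlap_join(a, a)
  expect_equal(ident$d_ij, nrow(a))
  expect_equal(ident$only_x, 0L)
  disj <- overlap_join(abc(c("A", "B")), abc(c("X", "Y")))
  expect_equal(disj$d_ij, 0L)
  # hash-join contract: one lookup per row, linear in input sizes
  expect_equal(attr(jn, "lookups"), nrow(a) + nrow(b))
  big <- abc(LETTERS[1:20])
  expect_equal(attr(overlap_join(big, big), "lookups"), 40L)
})

test_that("set metrics reproduce hand-computed values on {a,b,c} vs {b,c,d}", {
  jn <- overlap_join(abc(c("A", "B", "C")), abc(c("B", "C", "D")))
  sm <- set_metrics(jn)
  expect_equal(sm$jaccard, 0.5)
  expect_equal(sm$overlap_coeff, 2 / 3)
  expect_equal(sm$tversky, 2 / 3)        # alpha = beta = 0.5, Sorensen-Dice
  expect_equal(sm$rel_overlap_div, 2 / 9)
  idn <- set_metrics(overlap_join(abc(LETTERS[1:5]), abc(LETTERS[1:5])))
  expect_equal(idn$jaccard, 1)
  expect_equal(idn$tversky, 1)
  expect_equal(idn$rel_overlap_div, 1 / 5)
  dis <- set_metrics(overlap_join(abc(c("A", "B")), abc(c("X", "Y"))))
  expect_equal(unlist(dis), c(jaccard = 0, overlap_coeff = 0, tversky = 0,
                              rel_overlap_div = 0))
})

test_that("Morisita-Horn and companions match direct arithmetic", {
  x <- abc(c("A", "B", "C"), counts = c(6, 3, 1), sample = "x")
  y <- abc(c("A", "B", "C"), counts = c(1, 3, 6), sample = "y")
  fm <- frequency_metrics(overlap_join(x, y))
  expect_equal(fm$morisita_horn, 42 / 92, tolerance = 1e-12)
  idm <- frequency_metrics(overlap_join(x, x))
  expect_equal(idm$morisita_horn, 1, tolerance = 1e-12)
  expect_equal(idm$cosine, 1, tolerance = 1e-12)
  expect_equal(idm$geo_mean_overlap_freq, 1, tolerance = 1e-12)
  expect_equal(idm$clonewise_geo_sum, 1, tolerance = 1e-12)
  dism <- frequency_metrics(overlap_join(abc("A"), abc("Z")))
  expect_equal(dism$morisita_horn, 0)
  expect_equal(dism$clonewise_geo_sum, 0)
  # Pearson undefined below 2 shared clonotypes
  expect_true(is.na(frequency_metrics(overlap_join(abc("A"), abc("A")))$pearson))
})

test_that("V-usage Jensen-Shannon divergence hits its closed forms", {
  even <- make_table(c(1, 1), v = c("V1", "V2"))
  onlyv1 <- make_table(2, v = "V1")
  expect_equal(jsd_v_usage(even, even), 0, tolerance = 1e-12)
  expect_equal(jsd_v_usage(even, onlyv1),
               0.5 * 0.2075187 + 0.5 * 0.4150375, tolerance = 1e-6)
  disjoint <- make_table(c(1, 1), v = c("V8", "V9"))
  expect_equal(jsd_v_usage(even, disjoint), 1, tolerance = 1e-12)
  unres <- repertoire_table(data.frame(count = 1, cdr3nt = "AAA",
                                       cdr3aa = "K"), sample = "S")
  expect_error(jsd_v_usage(unres, even), "unresolved")
})

test_that("every metric is symmetric and bounded on random pairs", {
  for (seed in 1:15) {
    set.seed(seed)
    a <- random_table(sample(3:8, 1), sample = "a")
    b <- random_table(sample(3:8, 1), sample = "b")
    key <- clonotype_key("cdr3nt")
    mab <- overlap_metrics(a, b, key = key)
    mba <- overlap_metrics(b, a, key = key)
    for (nm in names(mab)) {
      if (is.na(mab[[nm]])) { expect_true(is.na(mba[[nm]])); next }
      expect_equal(mab[[nm]], mba[[nm]], tolerance = 1e-12, label = nm)
    }
    bounded <- c("morisita_horn", "jaccard", "overlap_coeff", "tversky",
                 "geo_mean_overlap_freq", "clonewise_geo_sum", "jsd_v_usage")
    for (nm in bounded) {
      if (is.na(mab[[nm]])) next
      expect_gte(mab[[nm]], -1e-12)
      expect_lte(mab[[nm]], 1 + 1e-12)
    }
  }
})

test_that("hash join agrees with the naive quadratic scan", {
  for (seed in 1:20) {
    set.seed(seed)
    a <- random_table(sample(2:6, 1), sample = "a")
    b <- random_table(sample(2:6, 1), sample = "b")
    key <- c("cdr3nt", "v", "j")
    got <- overlap_metrics(a, b, key = clonotype_key(key))
    want <- o_overlap(a, b, key)
    for (nm in names(want)) {
      if (is.na(want[[nm]])) { expect_true(is.na(got[[nm]])); next }
      expect_equal(got[[nm]], want[[nm]], tolerance = 1e-12, label = nm)
    }
  }
})

test_that("pairwise matrix is symmetric with a self-similarity diagonal", {
  set.seed(11)
  tables <- lapply(1:3, function(i) random_table(6, sample = paste0("S", i)))
  co <- merge_cohort(tables)
  m <- pairwise_matrix(co, "jaccard", key = clonotype_key("cdr3nt"))
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 3))
  same <- merge_cohort(lapply(1:3, function(i) {
    t <- tables[[1]]
    t$sample <- paste0("T", i)
    t
  }))
  expect_equal(unname(pairwise_matrix(same, "jaccard",
                                      key = clonotype_key("cdr3nt"))),
               matrix(1, 3, 3))
  expect_error(pairwise_matrix(merge_cohort(tables[1]), "jaccard"),
               "2 samples")
})
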