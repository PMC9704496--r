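test_that("diversity indices match hand-derived values", {
  t3 <- make_table(c(2, 1, 1))         # p = (0.5, 0.25, 0.25)
  expect_equal(shannon_wiener(t3), exp(1.5 * log(2)), tolerance = 1e-9)
  expect_equal(round(shannon_wiener(t3), 5), 2.82843)

  t <- make_table(c(6, 3, 1))
  sf <- simpson_family(t)
  expect_equal(sf$inv_simpson, 1 / 0.46, tolerance = 1e-12)
  expect_equal(sf$gini_simpson, 0.54, tolerance = 1e-12)
  expect_equal(d50(t), 100 / 3, tolerance = 1e-12)
  expect_equal(d50(make_table(10)), 100)
  expect_equal(d50(uniform_table(10)), 50)

  u4 <- uniform_table(4)
  expect_equal(normalized_shannon_wiener(u4), 4 / log(4), tolerance = 1e-12)
  expect_equal(normalized_shannon_wiener(u4, entropy_normalization = TRUE), 1,
               tolerance = 1e-12)
  expect_error(normalized_shannon_wiener(make_table(5)), "n < 2")
})

test_that("Chao1 handles singleton/doubleton structure and its variance", {
  t <- make_table(c(1, 1, 2, 3, 4))    # S=5, f1=2, f2=1
  ch <- chao1(t)
  expect_equal(unname(ch["estimate"]), 5.5)
  expect_equal(unname(ch["variance"]), 14)
  nos <- make_table(c(2, 2, 3))        # f1 = 0, f2 > 0
  expect_equal(unname(chao1(nos)["estimate"]), 3)
  expect_equal(unname(chao1(nos)["variance"]), 0)
  nof2 <- make_table(c(1, 3, 4))       # f2 = 0 -> variance undefined
  expect_true(is.na(chao1(nof2)["variance"]))
  # chao1 >= S always; equality iff f1 <= 1
  for (seed in 1:20) {
    r <- local({ set.seed(seed); random_table(sample(2:8, 1)) })
    ch <- chao1(r)
    expect_gte(unname(ch["estimate"]), nrow(r))
    if (sum(r$count == 1) <= 1)
      expect_equal(unname(ch["estimate"]), nrow(r))
  }
})

test_that("Gini coefficient follows the Lorenz-curve geometry", {
  two <- make_table(c(1, 9))           # freqs (0.1, 0.9)
  expect_equal(gini_coefficient(two), 0.4, tolerance = 1e-12)
  expect_equal(gini_coefficient(uniform_table(7)), 0, tolerance = 1e-12)
  for (seed in 1:15) {
    r <- local({ set.seed(seed); random_table(sample(2:8, 1)) })
    g <- gini_coefficient(r)
    expect_lt(g, 1 - 1 / nrow(r) + 1e-12)
    expect_gte(g, 0)
    # invariant to record order and uniform count scaling
    shuffled <- repertoire_table(
      local({ set.seed(seed + 100); as.data.frame(r)[sample(nrow(r)), ] }))
    expect_equal(gini_coefficient(shuffled), g, tolerance = 1e-12)
    scaled <- r
    scaled$count <- r$count * 7L
    scaled$freq <- scaled$count / sum(scaled$count)
    expect_equal(gini_coefficient(scaled), g, tolerance = 1e-12)
  }
})

test_that("Hill ordering inv_simpson <= shannon_wiener <= n holds", {
  for (seed in 1:25) {
    r <- local({ set.seed(seed); random_table(sample(2:8, 1)) })
    expect_lte(simpson_family(r)$inv_simpson, shannon_wiener(r) + 1e-9)
    expect_lte(shannon_wiener(r), nrow(r) + 1e-9)
    expect_equal(simpson_family(r)$gini_simpson,
                 1 - 1 / simpson_family(r)$inv_simpson, tolerance = 1e-12)
  }
})

test_that("diversity profile gathers every index consistently", {
  r <- local({ set.seed(3); random_table(8) })
  dp <- diversity_profile(r)
  expect_equal(dp$shannon_wiener, shannon_wiener(r))
  expect_equal(dp$inv_simpson, simpson_family(r)$inv_simpson)
  expect_equal(dp$chao1, unname(chao1(r)["estimate"]))
  expect_equal(dp$gini_coeff, gini_coefficient(r))
  single <- make_table(4)
  expect_true(is.na(diversity_profile(single)$normalized_shannon_wiener))
})
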