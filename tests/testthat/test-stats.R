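test_that("normality gate routes between t-test and rank-sum test", {
  gauss_a <- local({ set.seed(101); rnorm(20) })
  gauss_b <- local({ set.seed(102); rnorm(20) })
  cmp <- route_and_test(gauss_a, gauss_b)
  expect_identical(cmp$test_used, "t_test")
  expect_equal(cmp$p_raw,
               t.test(gauss_a, gauss_b, var.equal = TRUE)$p.value,
               tolerance = 1e-12)

  heavy <- local({ set.seed(103); exp(rnorm(20, sd = 3)) })
  cmp2 <- route_and_test(heavy, gauss_b)
  expect_identical(cmp2$test_used, "wilcoxon_rank_sum")
  expect_equal(cmp2$p_raw,
               suppressWarnings(wilcox.test(heavy, gauss_b,
                                            exact = FALSE)$p.value),
               tolerance = 1e-12)

  # routing is consistent with a reference Shapiro-Wilk gate
  for (seed in 1:10) {
    set.seed(seed)
    a <- if (seed %% 2) rnorm(15) else rexp(15)^3
    b <- rnorm(15)
    cmp3 <- route_and_test(a, b)
    both_normal <- shapiro.test(a)$p.value > 0.05 &&
      shapiro.test(b)$p.value > 0.05
    expect_identical(cmp3$test_used,
                     if (both_normal) "t_test" else "wilcoxon_rank_sum")
  }
})

test_that("identical groups yield p near 1 and degenerate inputs a sentinel", {
  vals <- c(1.2, 2.5, 3.1, 4.8, 5.5, 6.1, 7.9, 8.2, 9.4, 10.6)
  cmp <- route_and_test(vals, vals)
  expect_gt(cmp$p_raw, 0.95)
  const <- route_and_test(rep(2, 5), rep(2, 5))
  expect_identical(const$test_used, "degenerate")
  expect_true(is.na(const$p_raw))
  # constant but different groups still get a rank-sum p
  cd <- route_and_test(rep(1, 5), rep(2, 5))
  expect_identical(cd$test_used, "wilcoxon_rank_sum")
  expect_lt(cd$p_raw, 0.05)
  expect_error(route_and_test(1:2, 1:5), ">= 3")
})

test_that("Bonferroni correction is min(1, p*m) with validation", {
  expect_equal(bonferroni(c(0.01, 0.04)), c(0.02, 0.08))
  expect_equal(bonferroni(c(0.9, 0.7)), c(1, 1))
  expect_equal(bonferroni(0.03), 0.03)
  expect_error(bonferroni(c(0.5, 1.2)), "\\[0, 1\\]")
  for (seed in 1:5) {
    p <- local({ set.seed(seed); runif(sample(1:8, 1)) })
    adj <- bonferroni(p)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
    expect_equal(adj, pmin(1, p * length(p)), tolerance = 1e-15)
  }
})

test_that("metric comparison splits a cohort by a 2-level feature", {
  # group B is an exact read-doubled copy of group A
  base <- lapply(1:3, function(i)
    local({ set.seed(i + 200); random_table(8, sample = paste0("A", i)) }))
  doubled <- lapply(1:3, function(i) {
    t <- base[[i]]
    t$count <- t$count * 2L
    t$freq <- t$count / sum(t$count)
    t$sample <- paste0("B", i)
    t
  })
  md <- data.frame(sample = c(paste0("A", 1:3), paste0("B", 1:3)),
                   grp = rep(c("a", "b"), each = 3))
  co <- merge_cohort(c(base, doubled), md)
  res <- compare_metric_by_feature(co, c("read_count", "clonotype_count"),
                                   "grp")
  expect_equal(nrow(res), 2L)
  rc <- res[res$metric == "read_count", ]
  expect_equal(rc$mean_b / rc$mean_a, 2)          # construction: 2x reads
  cc <- res[res$metric == "clonotype_count", ]
  expect_equal(cc$mean_a, cc$mean_b)              # same clonotypes
  expect_true(all(res$m_comparisons == 2L))
  expect_equal(res$p_adjusted, pmin(1, res$p_raw * 2), tolerance = 1e-12)

  expect_error(compare_metric_by_feature(co, "read_count", "nope"), "nope")
  md3 <- md
  md3$grp[6] <- "c"
  co3 <- merge_cohort(c(base, doubled), md3)
  expect_error(compare_metric_by_feature(co3, "read_count", "grp"),
               "2 levels")
})

test_that("per-gene usage comparison corrects over the gene count", {
  set.seed(42)
  tables <- lapply(1:8, function(i)
    random_table(10, sample = sprintf("S%02d", i)))
  md <- data.frame(sample = vapply(tables, function(t) t$sample[1],
                                   character(1)),
                   grp = rep(c("x", "y"), each = 4))
  co <- merge_cohort(tables, md)
  res <- compare_metric_by_feature(co, "v_usage", "grp")
  g <- ncol(cohort_usage_table(co, "v"))
  expect_equal(nrow(res), g)
  expect_true(all(res$m_comparisons == g))
  ok <- !is.na(res$p_raw)
  expect_equal(res$p_adjusted[ok], pmin(1, res$p_raw[ok] * g),
               tolerance = 1e-12)
})
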