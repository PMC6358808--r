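test_that("partition counting is exact", {
  expect_identical(count_partitions(32, 22), 64512240)
  expect_identical(count_partitions(4, 2), 6)
  expect_identical(count_partitions(7, 0), 1)
  expect_identical(count_partitions(7, 7), 1)
  expect_error(count_partitions(4, 5), "exceed")
  expect_error(count_partitions(200, 100), "2\\^53")
})

test_that("systematic sampling produces the documented rank sets", {
  r <- systematic_sample(64512240, 310)
  expect_length(r, 208104)
  expect_identical(r[1], 0)
  expect_identical(r[length(r)], 64511930)
  expect_identical(systematic_sample(10, 1), as.numeric(0:9))
  r2 <- systematic_sample(100, 7)
  expect_length(r2, 15)
  expect_identical(r2[15], 98)
  expect_error(systematic_sample(10, 0), "step")
  expect_error(systematic_sample(10, 3, offset = 3), "offset")
})

test_that("combinadic unranking reproduces lexicographic enumeration", {
  expect_identical(unrank_combination(0, 4, 2), c(1L, 2L))
  expect_identical(unrank_combination(5, 4, 2), c(3L, 4L))
  expect_identical(unrank_combination(3, 5, 2),
                   unname(combn(5, 2)[, 4]))
  for (nk in list(c(5, 2), c(6, 3), c(9, 4), c(12, 5))) {
    n <- nk[1]; k <- nk[2]
    all_sets <- combn(n, k)
    for (r in 0:(ncol(all_sets) - 1))
      expect_identical(unrank_combination(r, n, k),
                       unname(all_sets[, r + 1]))
  }
  expect_error(unrank_combination(6, 4, 2), "rank")
})

test_that("AUROC equals the pair-counting oracle, ties included", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(rep(2, 6), rep(c(0, 1), 3)), 0.5)
  set.seed(61)
  for (r in 1:50) {
    n <- sample(4:12, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # force ties
    labels <- c(0, 1, sample(c(0, 1), n - 2, replace = TRUE))
    expect_equal(auroc(scores, labels == 1),
                 auroc_oracle(scores, labels == 1), tolerance = 1e-12)
  }
  expect_error(auroc(1:4, rep(1, 4)), "both classes")
})

test_that("Mann-Whitney AUROC p-values match the exact U null", {
  expect_equal(auroc_pvalue(0.5, 10, 10), 1.0)
  expect_equal(auroc_pvalue(1.0, 10, 10), 2 * dwilcox(0, 10, 10),
               tolerance = 1e-12)
  # symmetry p(A) = p(1 - A)
  for (a in c(0.64, 0.8, 0.93))
    expect_equal(auroc_pvalue(a, 8, 12), auroc_pvalue(1 - a, 8, 12),
                 tolerance = 1e-12)
  # one-sided tails partition the two-sided value
  expect_equal(auroc_pvalue(0.8, 10, 10),
               min(1, 2 * min(auroc_pvalue(0.8, 10, 10, "less"),
                              auroc_pvalue(0.8, 10, 10, "greater"))),
               tolerance = 1e-12)
  # normal approximation is close to exact near the boundary size
  expect_lt(abs(auroc_pvalue(0.7, 20, 20, exact_max = 400) -
                  auroc_pvalue(0.7, 20, 20, exact_max = 10)), 0.005)
  expect_error(auroc_pvalue(1.2, 5, 5), "0, 1")
})

test_that("paired AUROC null matches sign-flip enumeration", {
  # direct oracle: enumerate all sign patterns of a fixed score magnitude set
  set.seed(62)
  n <- 6
  e <- abs(rnorm(n))
  vs <- sapply(0:(2^n - 1), function(s) {
    signs <- ifelse(as.integer(intToBits(s)[1:n]) == 1, 1, -1)
    sum(outer(signs * e, signs * e, `+`) > 0)
  })
  for (v_obs in c(10, 18, 26, 36)) {
    expect_equal(auroc_pvalue_paired(v_obs / n^2, n, "greater"),
                 mean(vs >= v_obs), tolerance = 1e-12)
    expect_equal(auroc_pvalue_paired(v_obs / n^2, n, "less"),
                 mean(vs <= v_obs), tolerance = 1e-12)
  }
  expect_equal(auroc_pvalue_paired(0.5, 10), 1.0)
  # the paired null is wider than the two-sample null
  expect_gt(auroc_pvalue_paired(0.8, 10, "greater"),
            auroc_pvalue(0.8, 10, 10, "greater"))
  # normal approximation tracks the exact law beyond the enumeration limit
  expect_equal(auroc_pvalue_paired(0.7, 14, "greater", exact_max = 14),
               auroc_pvalue_paired(0.7, 14, "greater", exact_max = 5),
               tolerance = 0.02)
})

test_that("partition plans are internally consistent", {
  plan <- partition_plan()
  expect_identical(plan$total_partitions, 64512240)
  expect_length(plan$ranks, 208104)
  expect_true(all(diff(plan$ranks) == plan$step))
  small <- partition_plan(max_models = 2000)
  expect_lte(length(small$ranks), 2000)
  expect_gt(length(small$ranks), 1900)
  expect_error(partition_plan(n_pairs = 8, n_train_pairs = 8), "n_train")
})
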