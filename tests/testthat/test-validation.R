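test_that("partition evaluation is deterministic and leakage-free", {
  dat <- make_paired_data(12, 8, seed = 71)
  x <- within_pair_transform(dat$x, dat$pair)
  r1 <- evaluate_partition(x, dat$pair, dat$group, rank = 17,
                           n_train_pairs = 8)
  r2 <- evaluate_partition(x, dat$pair, dat$group, rank = 17,
                           n_train_pairs = 8)
  expect_identical(r1[c("auroc", "p_value", "vip")],
                   r2[c("auroc", "p_value", "vip")])
  expect_true(r1$auroc >= 0 && r1$auroc <= 1)
  expect_true(r1$p_value > 0 && r1$p_value <= 1)
  expect_equal(r1$n_test_pairs, 4)
})

test_that("a planted perfect separator yields AUROC 1 on every partition", {
  dat <- make_paired_data(10, 6, seed = 72)
  dat$x[dat$group == "LVR", 1] <- dat$x[dat$group == "LVR", 1] + 50
  x <- within_pair_transform(dat$x, dat$pair)
  for (r in c(0, 3, 100, count_partitions(10, 7) - 1)) {
    res <- evaluate_partition(x, dat$pair, dat$group, rank = r,
                              n_train_pairs = 7)
    expect_equal(res$auroc, 1.0)
  }
})

test_that("run_validation summarizes the stream and streams JSON lines", {
  dat <- make_paired_data(10, 6, shift = 2, n_informative = 3, seed = 73)
  plan <- partition_plan(n_pairs = 10, n_train_pairs = 7, max_models = 30)
  stream <- tempfile(fileext = ".jsonl")
  v <- run_validation(dat$x, dat$pair, dat$group, plan, stream = stream)
  expect_s3_class(v, "validation_summary")
  expect_equal(v$n_models, length(plan$ranks))
  expect_equal(v$fraction_significant,
               v$fraction_significantly_better +
                 v$fraction_significantly_worse)
  lines <- readLines(stream)
  expect_length(lines, v$n_models)
  first <- jsonlite::fromJSON(lines[1])
  expect_equal(first$auroc, v$results$auroc[1], tolerance = 1e-12)
  expect_named(first$vip, colnames(dat$x), ignore.order = TRUE)
  # summary determinism: identical data and plan give identical summaries
  v2 <- run_validation(dat$x, dat$pair, dat$group, plan)
  expect_equal(v$results, v2$results, tolerance = 1e-15)
})

test_that("decision rule selects variables only above both cutoffs", {
  # crafted stream at median AUROC 0.48: no selection
  res_low <- data.frame(rank = 0:99,
                        auroc = seq(0.28, 0.68, length.out = 100),
                        p_value = runif(100, 0.2, 0.9),
                        better = FALSE, worse = FALSE)
  s_low <- summarize_validation(res_low)
  expect_equal(s_low$median_auroc, 0.48)
  expect_false(s_low$decision)
  expect_length(s_low$selected_variables, 0)
  # crafted stream above both cutoffs: VIP > 1 variables are selected
  vipm <- cbind(signal1 = rep(1.8, 50), signal2 = rep(1.2, 50),
                noise = rep(0.4, 50))
  res_hi <- data.frame(rank = 0:49, auroc = rep(c(0.85, 0.9), 25),
                       p_value = rep(0.01, 50),
                       better = TRUE, worse = FALSE)
  s_hi <- summarize_validation(res_hi, vip = vipm)
  expect_true(s_hi$decision)
  expect_identical(s_hi$selected_variables, c("signal1", "signal2"))
})

test_that("a strong planted effect passes the decision rule end to end", {
  dat <- make_paired_data(32, 30, shift = 2, n_informative = 10, seed = 74)
  plan <- partition_plan(max_models = 60)
  v <- run_validation(dat$x, dat$pair, dat$group, plan)
  expect_gte(v$median_auroc, 0.8)
  expect_lte(v$median_p, 0.05)
  expect_true(v$decision)
  expect_true(all(paste0("V", 1:10) %in% v$selected_variables))
})

test_that("null data produce AUROCs centered at 0.5 across cohorts", {
  # marginal over replicate cohorts; a single cohort's models are correlated
  set.seed(75)
  aucs <- c()
  for (b in 1:40) {
    dat <- make_paired_data(16, 10, seed = 7500 + b)
    plan <- partition_plan(n_pairs = 16, n_train_pairs = 11,
                           max_models = 5)
    v <- run_validation(dat$x, dat$pair, dat$group, plan, keep_vip = FALSE)
    aucs <- c(aucs, v$results$auroc)
  }
  # exact paired-null sd of a single AUROC at 5 test pairs is ~0.26;
  # 200 correlated draws -> generous tolerance on the mean
  expect_lt(abs(mean(aucs) - 0.5), 0.08)
})

test_that("thinned plans give medians consistent with the full sweep", {
  dat <- make_paired_data(8, 6, shift = 1, n_informative = 3, seed = 76)
  full <- partition_plan(n_pairs = 8, n_train_pairs = 5, step = 1)
  expect_length(full$ranks, 56)
  v_full <- run_validation(dat$x, dat$pair, dat$group, full,
                           keep_vip = FALSE)
  thin <- partition_plan(n_pairs = 8, n_train_pairs = 5, step = 4)
  v_thin <- run_validation(dat$x, dat$pair, dat$group, thin,
                           keep_vip = FALSE)
  expect_lt(abs(v_full$median_auroc - v_thin$median_auroc), 0.15)
  # thinned ranks are a subset evaluated identically
  idx <- match(thin$ranks, full$ranks)
  expect_equal(v_thin$results$auroc, v_full$results$auroc[idx],
               tolerance = 1e-15)
})

test_that("plan/data mismatches abort", {
  dat <- make_paired_data(8, 5, seed = 77)
  plan <- partition_plan(n_pairs = 10, n_train_pairs = 7, max_models = 5)
  expect_error(run_validation(dat$x, dat$pair, dat$group, plan),
               "pairs")
})
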