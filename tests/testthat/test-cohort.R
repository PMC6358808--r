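test_that("default cohort has the expected structure", {
  sim <- generate_cohort(cohort_config(seed = 11))
  expect_equal(nrow(sim$cohort), 64L)
  expect_equal(sum(sim$cohort$group == "LVR"), 32L)
  expect_equal(ncol(sim$matrix$values), 188L)
  expect_true(all(sim$matrix$values > 0))
  # pair-id bijection: each pair appears once per group
  tab <- table(sim$cohort$pair_id, sim$cohort$group)
  expect_true(all(tab == 1L))
  expect_false(anyDuplicated(sim$cohort$subject_id) > 0)
  # censor flags agree with the limits by construction
  expect_identical(sim$matrix$censored, plsval:::censor_flags(sim$matrix))
})

test_that("generation is deterministic under a fixed seed", {
  a <- generate_cohort(cohort_config(seed = 5))
  b <- generate_cohort(cohort_config(seed = 5))
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$cohort, b$cohort)
  c <- generate_cohort(cohort_config(seed = 6))
  expect_false(identical(a$matrix$values, c$matrix$values))
})

test_that("configured group means are recovered across replicate cohorts", {
  # SDMA 0.57 vs 0.52 and SM C20:2 0.29 vs 0.25 umol/L over 200 cohorts
  # (100 antithetic pairs for Monte Carlo variance reduction)
  reps <- 100
  acc <- matrix(0, 2 * reps, 4)
  grab <- function(sim) {
    lvr <- sim$cohort$group == "LVR"
    c(mean(sim$matrix$values[lvr, "SDMA"]),
      mean(sim$matrix$values[!lvr, "SDMA"]),
      mean(sim$matrix$values[lvr, "SM C20:2"]),
      mean(sim$matrix$values[!lvr, "SM C20:2"]))
  }
  for (r in seq_len(reps)) {
    cfg <- cohort_config(seed = 1000 + r)
    acc[2 * r - 1, ] <- grab(generate_cohort(cfg))
    acc[2 * r, ] <- grab(generate_cohort(cfg, antithetic = TRUE))
  }
  grand <- colMeans(acc)
  n <- 2 * reps * 32
  se <- c(0.15, 0.07, 0.07, 0.05) / sqrt(n)
  expect_lt(abs(grand[1] - 0.57), 2 * se[1])
  expect_lt(abs(grand[2] - 0.52), 2 * se[2])
  expect_lt(abs(grand[3] - 0.29), 2 * se[3])
  expect_lt(abs(grand[4] - 0.25), 2 * se[4])
})

test_that("group-mean difference converges to the configured shift", {
  eff <- data.frame(name = "AA C01", lvr_mean = 2.0, lvr_sd = 0.4,
                    ctrl_mean = 1.5, ctrl_sd = 0.3)
  cfg <- small_config(n_pairs = 512L, seed = 42L, retained = 3L,
                      effect_spec = eff)
  sim <- generate_cohort(cfg)
  lvr <- sim$cohort$group == "LVR"
  d <- mean(sim$matrix$values[lvr, "AA C01"]) -
    mean(sim$matrix$values[!lvr, "AA C01"])
  # sd of the difference of two 512-sample means ~ sqrt(.4^2+.3^2)/sqrt(512)
  expect_lt(abs(d - 0.5), 3 * sqrt(0.4^2 + 0.3^2) / sqrt(512))
})

test_that("null mode removes all group effects", {
  cfg <- cohort_config(n_pairs = 256L, seed = 8L)
  sim <- null_cohort(cfg)
  lvr <- sim$cohort$group == "LVR"
  d <- mean(sim$matrix$values[lvr, "SDMA"]) -
    mean(sim$matrix$values[!lvr, "SDMA"])
  expect_lt(abs(d), 3 * sqrt(2) * 0.07 / sqrt(256))
  # biomarkers nulled too
  db <- mean(sim$cohort$ck_peak[lvr]) - mean(sim$cohort$ck_peak[!lvr])
  expect_lt(abs(db), 3 * sqrt(2) * 1615 / sqrt(256))
})

test_that("null-mode generator has calibrated type-I error", {
  # paired t-test on one metabolite across replicate null cohorts
  reps <- 400
  rej <- 0
  for (r in seq_len(reps)) {
    sim <- null_cohort(small_config(n_pairs = 8L, seed = 5000 + r,
                                    retained = 1L))
    lvr <- sim$cohort$group == "LVR"
    d <- sim$matrix$values[lvr, 1] - sim$matrix$values[!lvr, 1]
    if (t.test(d)$p.value <= 0.05) rej <- rej + 1
  }
  expect_lt(abs(rej / reps - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("censoring calibration matches the configured probabilities", {
  cfg <- cohort_config(n_pairs = 512L, seed = 3L)
  sim <- generate_cohort(cfg)
  ret <- sim$matrix$annotations$name %in%
    with(plsval:::panel_metabolites(cfg$panel_spec, cfg$effect_spec),
         name[designed_retained])
  frac_ret <- mean(sim$matrix$censored[, ret])
  frac_fail <- mean(sim$matrix$censored[, !ret])
  n_ret <- sum(ret) * 1024; n_fail <- sum(!ret) * 1024
  expect_lt(abs(frac_ret - 0.02), 4 * sqrt(0.02 * 0.98 / n_ret))
  expect_lt(abs(frac_fail - 0.6), 4 * sqrt(0.6 * 0.4 / n_fail))
})

test_that("configuration errors are caught", {
  expect_error(cohort_config(pair_correlation = 1), "pair_correlation")
  expect_error(cohort_config(effect_spec = within(default_effect_spec(),
                                                  lvr_sd[1] <- 0)),
               "standard deviations")
  bad_panel <- data.frame(family = "x", total = 2L, retained = 5L)
  expect_error(cohort_config(panel_spec = bad_panel), "panel_spec")
})
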