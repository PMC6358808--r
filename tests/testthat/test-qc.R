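make_cm <- function(values, lloq, uloq, family = "amino acids") {
  ann <- data.frame(name = colnames(values), family = family,
                    lloq = lloq, uloq = uloq, stringsAsFactors = FALSE)
  conc_matrix(values, ann)
}

test_that("censor flags follow the strict below/above rule", {
  v <- matrix(c(0.5, 0.49, 10, 10.01, 5, NA), 3, 2,
              dimnames = list(NULL, c("a", "b")))
  cm <- flag_out_of_range(make_cm(v, lloq = c(0.5, 0.5),
                                  uloq = c(10, 10)))
  # value exactly at LLOQ or ULOQ is accurately measured; strictly below is
  # flagged
  expect_identical(unname(cm$censored[, "a"]), c(FALSE, TRUE, FALSE))
  # above ULOQ and missing values are flagged
  expect_identical(unname(cm$censored[, "b"]), c(TRUE, FALSE, TRUE))
  # values are never altered
  expect_identical(cm$values, v)
})

test_that("planted violations are flagged exactly", {
  set.seed(21)
  v <- matrix(runif(200, 1, 9), 20, 10,
              dimnames = list(NULL, paste0("m", 1:10)))
  planted <- matrix(FALSE, 20, 10)
  low <- cbind(sample(20, 15, TRUE), sample(10, 15, TRUE))
  v[low] <- runif(nrow(low), 0, 0.4); planted[low] <- TRUE
  high <- cbind(sample(20, 8, TRUE), sample(10, 8, TRUE))
  v[high] <- runif(nrow(high), 11, 20); planted[high] <- TRUE
  cm <- flag_out_of_range(make_cm(v, rep(0.5, 10), rep(10, 10)))
  expect_identical(unname(cm$censored), planted)
})

test_that("missing limits raise an error naming the metabolite", {
  v <- matrix(1, 2, 2, dimnames = list(NULL, c("good", "broken")))
  ann <- data.frame(name = c("good", "broken"), family = "x",
                    lloq = c(0.1, 0.2), uloq = c(10, 20))
  cm <- make_cm(v, c(0.1, 0.2), c(10, 20))
  cm$annotations$lloq[2] <- NA
  expect_error(flag_out_of_range(cm), "broken")
})

test_that("the 20% threshold is strictly 'more than'", {
  # 64 samples: 13 flagged cells (20.3%) dropped, 12 (18.75%) kept
  v <- matrix(5, 64, 2, dimnames = list(NULL, c("drop", "keep")))
  v[1:13, 1] <- 0.1
  v[1:12, 2] <- 0.1
  cm <- flag_out_of_range(make_cm(v, c(0.5, 0.5), c(10, 10)))
  filt <- filter_metabolites(cm)
  expect_identical(filt$report$retained, c(FALSE, TRUE))
  expect_identical(colnames(filt$matrix$values), "keep")
  # boundary: exactly 20% out of range is retained
  v2 <- matrix(5, 10, 1, dimnames = list(NULL, "edge"))
  v2[1:2, 1] <- 0.1
  f2 <- filter_metabolites(flag_out_of_range(make_cm(v2, 0.5, 10)))
  expect_true(f2$report$retained)
})

test_that("clean matrices pass untouched and the filter is idempotent", {
  set.seed(4)
  v <- matrix(runif(60, 1, 9), 10, 6,
              dimnames = list(NULL, paste0("m", 1:6)))
  cm <- flag_out_of_range(make_cm(v, rep(0.5, 6), rep(10, 6)))
  f1 <- filter_metabolites(cm)
  expect_equal(attr(f1$report, "n_retained"), attr(f1$report, "n_input"))
  f2 <- filter_metabolites(f1$matrix)
  expect_identical(f2$matrix$values, f1$matrix$values)
})

test_that("retention is permutation invariant and order preserving", {
  set.seed(5)
  v <- matrix(runif(120, 1, 9), 12, 10,
              dimnames = list(NULL, paste0("m", 1:10)))
  v[1:6, c(2, 7)] <- 0.01  # 50% censored in two metabolites
  cm <- flag_out_of_range(make_cm(v, rep(0.5, 10), rep(10, 10)))
  f <- filter_metabolites(cm)
  perm <- sample(10)
  cmp <- subset_metabolites(cm, perm)
  fp <- filter_metabolites(cmp)
  expect_setequal(colnames(fp$matrix$values), colnames(f$matrix$values))
  # column order of the permuted input is preserved among retained columns
  expect_identical(colnames(fp$matrix$values),
                   colnames(cmp$values)[fp$report$retained])
})

test_that("default synthetic panel retains 142 of 188 with the family breakdown", {
  sim <- generate_cohort(cohort_config(seed = 2))
  filt <- filter_metabolites(flag_out_of_range(sim$matrix))
  expect_equal(attr(filt$report, "n_input"), 188L)
  expect_equal(attr(filt$report, "n_retained"), 142L)
  by_fam <- tapply(filt$report$retained, filt$report$family, sum)
  expect_equal(by_fam[["acylcarnitines"]], 12L)
  expect_equal(by_fam[["amino acids"]], 21L)
  expect_equal(by_fam[["biogenic amines"]], 12L)
  expect_equal(by_fam[["lysophosphatidylcholines"]], 12L)
  expect_equal(by_fam[["phosphatidylcholines"]], 70L)
  expect_equal(by_fam[["sphingomyelins"]], 14L)
  expect_equal(by_fam[["hexoses"]], 1L)
})

test_that("an empty retained set is an explicit error", {
  v <- matrix(0.01, 10, 2, dimnames = list(NULL, c("a", "b")))
  cm <- flag_out_of_range(make_cm(v, c(0.5, 0.5), c(10, 10)))
  expect_error(filter_metabolites(cm), "no metabolite passes")
})
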