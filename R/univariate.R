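#' Normality-gated choice of two-group test
#'
#' Applies the Shapiro-Wilk test to decide between the parametric and the
#' rank-based comparison. In paired mode the gate is applied to the
#' within-pair differences `a - b`; in unpaired mode both groups must look
#' normal for the parametric branch to be taken. Constant input, for which
#' Shapiro-Wilk is undefined, falls through to the nonparametric branch
#' with a warning.
#'
#' @param values_a,values_b Numeric sample vectors; in paired mode they must
#'   be pair-aligned and of equal length.
#' @param paired Logical.
#' @param normality_alpha Level of the Shapiro-Wilk gate: the parametric
#'   branch is taken iff normality is not rejected (p > `normality_alpha`).
#'   Default 0.05.
#' @param var_equal Unpaired parametric flavour: `FALSE` (default) selects
#'   Welch's unequal-variance t-test, `TRUE` the pooled-variance Student
#'   test.
#' @return One of `"paired t-test"`, `"wilcoxon signed-rank"`,
#'   `"welch t-test"`, `"student t-test"`, `"mann-whitney"`.
#' @examples
#' set.seed(1)
#' choose_test(rnorm(32), rnorm(32), paired = TRUE)
#' @export
choose_test <- function(values_a, values_b, paired,
                        normality_alpha = 0.05, var_equal = FALSE) {
  if (length(values_a) < 3L || length(values_b) < 3L)
    stop("at least 3 observations per group are required")
  sw_p <- function(v) {
    if (length(unique(v)) < 3L) {
      warning("constant or near-constant input: Shapiro-Wilk undefined, ",
              "using the nonparametric branch")
      return(0)
    }
    tryCatch(stats::shapiro.test(v)$p.value,
             error = function(e) {
               warning("Shapiro-Wilk failed (", conditionMessage(e),
                       "): using the nonparametric branch")
               0
             })
  }
  if (paired) {
    if (length(values_a) != length(values_b))
      stop("paired mode requires equal-length, pair-aligned vectors")
    normal <- sw_p(values_a - values_b) > normality_alpha
    if (normal) "paired t-test" else "wilcoxon signed-rank"
  } else {
    normal <- sw_p(values_a) > normality_alpha &&
      sw_p(values_b) > normality_alpha
    if (normal) {
      if (var_equal) "student t-test" else "welch t-test"
    } else "mann-whitney"
  }
}

# run the selected test; returns the raw p-value.
run_chosen_test <- function(a, b, test) {
  n <- length(a)
  switch(test,
    "paired t-test" = stats::t.test(a, b, paired = TRUE)$p.value,
    "wilcoxon signed-rank" = {
      d <- a - b
      if (all(d == 0)) return(1)  # identical groups: no evidence either way
      ok_exact <- n <= 25L && !any(d == 0) && !anyDuplicated(abs(d))
      suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                          exact = ok_exact,
                                          correct = TRUE)$p.value)
    },
    "welch t-test" = stats::t.test(a, b, var.equal = FALSE)$p.value,
    "student t-test" = stats::t.test(a, b, var.equal = TRUE)$p.value,
    "mann-whitney" = {
      ok_exact <- length(a) * length(b) <= 625L &&
        !anyDuplicated(c(a, b))
      suppressWarnings(stats::wilcox.test(a, b, exact = ok_exact,
                                          correct = TRUE)$p.value)
    },
    stop("unknown test id: ", test))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts a vector of raw p-values with the Benjamini-Hochberg (1995)
#' step-up procedure controlling the false discovery rate, via
#' [stats::p.adjust()]. Adjusted values are monotone in the ranks of the raw
#' values and capped at 1.
#'
#' @param p_values Numeric vector of probabilities in `[0, 1]`.
#' @return Adjusted p-values, same length and order as the input.
#' @examples
#' adjust_benjamini(c(0.01, 0.02, 0.03, 0.04))
#' @export
adjust_benjamini <- function(p_values) {
  if (!is.numeric(p_values))
    stop("'p_values' must be numeric")
  ok <- is.na(p_values) | (p_values >= 0 & p_values <= 1)
  if (!all(ok))
    stop("p-values outside [0, 1] at position(s): ",
         paste(which(!ok), collapse = ", "))
  stats::p.adjust(p_values, method = "BH")
}

#' Paired or unpaired univariate comparison of all variables
#'
#' Compares the two groups variable by variable, choosing each test with the
#' Shapiro-Wilk gate of [choose_test()], and appends Benjamini-Hochberg
#' adjusted p-values. All variables passed in one call form a single
#' adjustment family, so metabolites and routine biomarkers should be
#' submitted in separate calls.
#'
#' In paired mode rows are aligned by `pair`: every pair id must occur
#' exactly once per group.
#'
#' @param x Numeric matrix or data.frame (samples x variables), or a
#'   [conc_matrix].
#' @param group Factor or character vector of group labels, two levels, one
#'   per sample. The first level after sorting (e.g. `"LVR"` before
#'   `"noLVR"`) is treated as the case group.
#' @param pair Pair identifiers, required when `paired = TRUE`.
#' @param paired Logical; defaults to `TRUE` when `pair` is given.
#' @param normality_alpha Level of the Shapiro-Wilk gate.
#' @param var_equal Use the pooled-variance Student test instead of Welch in
#'   the unpaired parametric branch.
#' @param alpha Significance level applied to the adjusted p-values.
#' @return A data.frame of class `univariate_results` with one row per
#'   variable: group means and sds, the test used, `p_raw`, `p_adj` and
#'   `significant` (adjusted p <= `alpha`).
#' @examples
#' sim <- generate_cohort(cohort_config(seed = 3))
#' filt <- filter_metabolites(sim$matrix)
#' res <- compare_groups(filt$matrix, sim$cohort$group,
#'                       pair = sim$cohort$pair_id)
#' head(res[order(res$p_raw), ])
#' @export
compare_groups <- function(x, group, pair = NULL, paired = !is.null(pair),
                           normality_alpha = 0.05, var_equal = FALSE,
                           alpha = 0.05) {
  if (inherits(x, "conc_matrix")) x <- x$values
  x <- as.matrix(x)
  group <- as.character(group)
  lev <- sort(unique(group))
  if (length(lev) != 2L) stop("'group' must have exactly two levels")
  if (nrow(x) != length(group)) stop("one group label per sample required")
  ia <- which(group == lev[1]); ib <- which(group == lev[2])
  if (paired) {
    if (is.null(pair)) stop("'pair' is required in paired mode")
    pa <- pair[ia]; pb <- pair[ib]
    if (length(pa) != length(pb) || !setequal(pa, pb) ||
        anyDuplicated(pa) || anyDuplicated(pb))
      stop("unmatched pair ids: every pair needs one sample per group")
    ib <- ib[match(pa, pb)]  # align group-2 rows to group-1 pair order
  }
  vars <- colnames(x)
  if (is.null(vars)) vars <- paste0("V", seq_len(ncol(x)))
  res <- lapply(seq_len(ncol(x)), function(j) {
    a <- x[ia, j]; b <- x[ib, j]
    test <- withCallingHandlers(
      choose_test(a, b, paired = paired, normality_alpha = normality_alpha,
                  var_equal = var_equal),
      warning = function(w) invokeRestart("muffleWarning"))
    data.frame(variable = vars[j],
               mean_a = mean(a), sd_a = stats::sd(a),
               mean_b = mean(b), sd_b = stats::sd(b),
               test = test, p_raw = run_chosen_test(a, b, test),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  names(res)[2:5] <- c(paste0(c("mean_", "sd_"), lev[1]),
                       paste0(c("mean_", "sd_"), lev[2]))
  res$p_adj <- adjust_benjamini(res$p_raw)
  res$significant <- res$p_adj <= alpha
  attr(res, "groups") <- lev
  attr(res, "paired") <- paired
  attr(res, "alpha") <- alpha
  class(res) <- c("univariate_results", "data.frame")
  res
}

#' @export
`[.univariate_results` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) class(out) <- "data.frame"
  out
}

#' @export
print.univariate_results <- function(x, ...) {
  cat(sprintf("Univariate %s comparison, %d variables (%s vs %s), BH-adjusted\n",
              if (attr(x, "paired")) "paired" else "unpaired", nrow(x),
              attr(x, "groups")[1], attr(x, "groups")[2]))
  cat(sprintf("  significant at adjusted p <= %.2f: %d\n",
              attr(x, "alpha"), sum(x$significant)))
  print.data.frame(utils::head(x[order(x$p_raw), ], 10), digits = 3,
                   row.names = FALSE)
  if (nrow(x) > 10) cat("  ... (", nrow(x) - 10, "more )\n")
  invisible(x)
}
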