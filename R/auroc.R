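#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC with midrank tie handling: the fraction
#' of (positive, negative) score pairs in which the positive scores higher,
#' ties counting one half.
#'
#' @param scores Numeric prediction scores, larger meaning more positive.
#' @param labels Binary labels: logical, 0/1, or two-level factor/character
#'   (the level sorted last is positive).
#' @return AUROC in `[0, 1]`.
#' @examples
#' auroc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
#' @export
auroc <- function(scores, labels) {
  pos <- as_binary_labels(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute an AUROC")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    lev <- sort(unique(labels))
    if (length(lev) > 2L) stop("labels must have at most two levels")
    return(labels == lev[length(lev)])
  }
  if (!all(labels %in% c(0, 1))) stop("numeric labels must be coded 0/1")
  labels == 1
}

#' Significance of an AUROC against the mean model (independent samples)
#'
#' Tail probability that the mean model -- random prediction of the class
#' labels -- produces an AUROC as extreme as observed, via the null
#' distribution of the Mann-Whitney U statistic `U = auroc * n_pos * n_neg`.
#' The exact U distribution is used when `n_pos * n_neg <= exact_max`
#' (default 400); beyond that, the normal approximation with continuity
#' correction. The two-sided p-value is symmetric, `p(A) = p(1 - A)`, and
#' equals 1 at `A = 0.5`.
#'
#' This null assumes the test scores are exchangeable *between* independent
#' samples. For scores from a multilevel within-pair model, whose test
#' scores are antisymmetric within matched pairs, use
#' [auroc_pvalue_paired()].
#'
#' @param auroc Observed AUROC in `[0, 1]`.
#' @param n_pos,n_neg Test-set class sizes.
#' @param alternative `"two.sided"` (default), `"greater"` (upper tail,
#'   AUROC above 0.5) or `"less"`.
#' @param exact_max Largest `n_pos * n_neg` for which the exact U
#'   distribution is used.
#' @return A probability in `(0, 1]`.
#' @examples
#' auroc_pvalue(1.0, 10, 10)   # 2 / choose(20, 10)
#' auroc_pvalue(0.5, 10, 10)   # 1
#' @export
auroc_pvalue <- function(auroc, n_pos, n_neg,
                         alternative = c("two.sided", "greater", "less"),
                         exact_max = 400) {
  alternative <- match.arg(alternative)
  if (!is.numeric(auroc) || auroc < 0 || auroc > 1)
    stop("'auroc' must lie in [0, 1]")
  if (n_pos < 1L || n_neg < 1L) stop("both class sizes must be >= 1")
  mn <- n_pos * n_neg
  u <- auroc * mn
  if (mn <= exact_max) {
    lower <- stats::pwilcox(floor(u), n_pos, n_neg)
    upper <- 1 - stats::pwilcox(ceiling(u) - 1, n_pos, n_neg)
  } else {
    mu <- mn / 2
    sd <- sqrt(mn * (n_pos + n_neg + 1) / 12)
    lower <- stats::pnorm((u - mu + 0.5) / sd)
    upper <- stats::pnorm(-(u - mu - 0.5) / sd)
  }
  tail_p(lower, upper, alternative)
}

tail_p <- function(lower, upper, alternative) {
  switch(alternative,
         two.sided = min(1, 2 * min(lower, upper)),
         greater = upper,
         less = lower)
}

# Exact null distribution of the AUROC numerator for paired antisymmetric
# scores. With n matched test pairs the scores are {e_i} for positives and
# {-e_i} for negatives (up to a common shift), so
#   V = auroc * n^2 = #{(i, j) : e_i + e_j > 0}
# counted over ordered pairs including i = j. The count of positive Walsh
# averages #{i <= j : e_i + e_j > 0} is the Wilcoxon signed-rank statistic
# W+, hence V = 2 W+ - (number of positive e_i) and the null law of V is
# distribution-free over the 2^n equiprobable sign patterns of symmetric
# continuous e. Enumerated exactly and cached per n.
walsh_null_env <- new.env(parent = emptyenv())

walsh_auroc_null <- function(n_pairs) {
  key <- as.character(n_pairs)
  if (!is.null(walsh_null_env[[key]])) return(walsh_null_env[[key]])
  if (n_pairs > 20L) stop("exact enumeration limited to 20 pairs")
  counts <- numeric(n_pairs^2 + 1L)
  ranks <- seq_len(n_pairs)
  for (s in 0:(2^n_pairs - 1)) {
    bits <- as.integer(intToBits(s)[ranks]) == 1L
    v <- 2L * sum(ranks[bits]) - sum(bits)
    counts[v + 1L] <- counts[v + 1L] + 1
  }
  d <- counts / 2^n_pairs
  res <- list(density = d, lower = cumsum(d), upper = rev(cumsum(rev(d))))
  walsh_null_env[[key]] <- res
  res
}

#' Significance of an AUROC against the mean model (matched test pairs)
#'
#' Tail probability of the observed AUROC under the exact null appropriate
#' for predictions of a within-pair (multilevel) model evaluated on matched
#' test pairs. Such predictions are antisymmetric within each pair, so the
#' AUROC numerator equals the number of positive Walsh averages of the pair
#' scores (counted over ordered pairs), whose null distribution over random
#' sign flips is the signed-rank law -- notably wider than the two-sample
#' Mann-Whitney null, which would overstate significance on paired scores.
#' Exact enumeration over the `2^n` sign patterns is used for
#' `n_pairs <= exact_max`; beyond that a normal approximation with
#' continuity correction (mean `n^2/2`, variance
#' `n(n+1)(2n+1)/6 + n/4 - n(n+1)/2`).
#'
#' @param auroc Observed AUROC in `[0, 1]` computed on `n_pairs` positive
#'   and `n_pairs` negative scores.
#' @param n_pairs Number of matched test pairs.
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @param exact_max Largest `n_pairs` for exact enumeration (default 14).
#' @return A probability in `(0, 1]`.
#' @examples
#' auroc_pvalue_paired(0.9, 10, alternative = "greater")
#' @export
auroc_pvalue_paired <- function(auroc, n_pairs,
                                alternative = c("two.sided", "greater",
                                                "less"),
                                exact_max = 14L) {
  alternative <- match.arg(alternative)
  if (!is.numeric(auroc) || auroc < 0 || auroc > 1)
    stop("'auroc' must lie in [0, 1]")
  if (n_pairs < 2L) stop("'n_pairs' must be >= 2")
  v <- auroc * n_pairs^2
  if (n_pairs <= exact_max) {
    null <- walsh_auroc_null(n_pairs)
    lower <- null$lower[floor(v) + 1L]
    upper <- null$upper[ceiling(v) + 1L]
  } else {
    n <- n_pairs
    mu <- n^2 / 2
    sd <- sqrt(n * (n + 1) * (2 * n + 1) / 6 + n / 4 - n * (n + 1) / 2)
    lower <- stats::pnorm((v - mu + 0.5) / sd)
    upper <- stats::pnorm(-(v - mu - 0.5) / sd)
  }
  tail_p(lower, upper, alternative)
}
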