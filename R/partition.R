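#' Exact number of train/test partitions
#'
#' Binomial coefficient `choose(n, k)`: the number of ways to allocate `k`
#' of `n` matched pairs to the training set. Exact as long as the result is
#' below 2^53 (the integer-exact range of double precision); larger counts
#' raise an error rather than silently rounding.
#'
#' @param n Number of pairs.
#' @param k Number of training pairs.
#' @return The exact count as a double.
#' @examples
#' count_partitions(32, 22)  # 64512240
#' @export
count_partitions <- function(n, k) {
  if (k < 0 || n < 0) stop("'n' and 'k' must be non-negative")
  if (k > n) stop("'k' must not exceed 'n'")
  v <- choose(n, k)
  if (v >= 2^53)
    stop("partition count exceeds 2^53 and cannot be represented exactly")
  round(v)
}

#' Systematic (every step-th) sampling of partition ranks
#'
#' Thins the lexicographic enumeration `0, 1, ..., total - 1` to the ranks
#' `offset, offset + step, ...`, i.e. every `step`-th combination, the
#' systematic column sampling used to make an exhaustive partition sweep
#' computationally feasible.
#'
#' @param total Total number of partitions.
#' @param step Sampling period (>= 1).
#' @param offset First rank, `0 <= offset < step`.
#' @return Strictly increasing numeric vector of 0-based ranks, of length
#'   `ceiling((total - offset) / step)`.
#' @examples
#' length(systematic_sample(64512240, 310))  # 208104
#' @export
systematic_sample <- function(total, step, offset = 0) {
  if (!is.numeric(step) || step < 1) stop("'step' must be >= 1")
  step <- round(step)
  if (offset < 0 || offset >= step) stop("'offset' must satisfy 0 <= offset < step")
  if (total < 1) stop("'total' must be >= 1")
  if (offset >= total) return(numeric(0))
  seq(from = offset, to = total - 1, by = step)
}

#' Lexicographic unranking of a k-combination
#'
#' Returns the `rank`-th (0-based) k-subset of `{1, ..., n}` in
#' lexicographic order, by combinadic decomposition: the enumeration is
#' never materialized, so any of the tens of millions of partitions is
#' reachable in O(n) time and O(1) memory.
#'
#' @param rank 0-based lexicographic rank, `0 <= rank < choose(n, k)`.
#' @param n Set size.
#' @param k Subset size.
#' @return Strictly increasing integer vector of length `k` with elements in
#'   `1..n`.
#' @examples
#' unrank_combination(0, 4, 2)  # 1 2
#' unrank_combination(5, 4, 2)  # 3 4
#' @export
unrank_combination <- function(rank, n, k) {
  total <- count_partitions(n, k)
  if (rank < 0 || rank >= total)
    stop("'rank' must lie in [0, ", format(total, scientific = FALSE), ")")
  out <- integer(k)
  r <- rank
  x <- 0L  # 0-based candidate element
  for (i in seq_len(k)) {
    repeat {
      c_block <- choose(n - 1L - x, k - i)
      if (c_block > r) break
      r <- r - c_block
      x <- x + 1L
    }
    out[i] <- x + 1L
    x <- x + 1L
  }
  out
}

#' Plan a systematically thinned sweep of pair-level partitions
#'
#' Defines the exhaustive lexicographic enumeration of train/test splits at
#' the level of matched pairs (both members of a pair always travel
#' together) and its systematic thinning. The default reproduces the full
#' design for a 32-pair cohort: 22 training pairs, 10 test pairs,
#' `choose(32, 22) = 64,512,240` possible models, thinned every 310 ranks to
#' 208,104 evaluated models.
#'
#' @param n_pairs Number of matched pairs (default 32).
#' @param n_train_pairs Pairs allocated to the training set (default 22).
#' @param step Systematic sampling period (default 310). Ignored when
#'   `max_models` is given.
#' @param offset First sampled rank (default 0).
#' @param max_models If non-`NULL`, choose the smallest `step` whose thinned
#'   plan has at most `max_models` ranks.
#' @return An object of class `partition_plan`: `n_pairs`, `n_train_pairs`,
#'   `n_test_pairs`, `total_partitions`, `step`, `offset`, `ranks`.
#' @examples
#' plan <- partition_plan()
#' plan
#' small <- partition_plan(max_models = 2000)
#' length(small$ranks)
#' @export
partition_plan <- function(n_pairs = 32L, n_train_pairs = 22L, step = 310L,
                           offset = 0L, max_models = NULL) {
  n_pairs <- as.integer(n_pairs); n_train_pairs <- as.integer(n_train_pairs)
  if (n_train_pairs >= n_pairs || n_train_pairs < 1L)
    stop("need 1 <= n_train_pairs < n_pairs")
  total <- count_partitions(n_pairs, n_train_pairs)
  if (!is.null(max_models)) {
    if (max_models < 1L) stop("'max_models' must be >= 1")
    step <- ceiling(total / max_models)
    while (ceiling((total - offset) / step) > max_models) step <- step + 1
  }
  ranks <- systematic_sample(total, step, offset)
  structure(list(n_pairs = n_pairs, n_train_pairs = n_train_pairs,
                 n_test_pairs = n_pairs - n_train_pairs,
                 total_partitions = total, step = step, offset = offset,
                 ranks = ranks),
            class = "partition_plan")
}

#' @export
print.partition_plan <- function(x, ...) {
  cat(sprintf("Partition plan: %d pairs -> %d train / %d test\n",
              x$n_pairs, x$n_train_pairs, x$n_test_pairs))
  cat(sprintf("  total partitions: %s;  step %d, offset %d -> %s models\n",
              format(x$total_partitions, big.mark = ",",
                     scientific = FALSE),
              x$step, x$offset,
              format(length(x$ranks), big.mark = ",")))
  invisible(x)
}
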