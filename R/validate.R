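#' Evaluate one train/test partition
#'
#' Unranks the partition, fits a PLS-DA model on the training pairs (scaling
#' fitted on the training block only), predicts the held-out test samples,
#' and scores the model by test-set AUROC, its tail probability under the
#' mean model, and the VIP vector.
#'
#' The reported `p_value` is the one-sided tail probability of the observed
#' AUROC in its own direction -- the probability that the mean model,
#' randomly predicting patient status, performs at least as well (or as
#' poorly) as the model at hand. A model is called significantly better
#' (worse) than the mean model when its upper (lower) tail probability is at
#' or below the chosen level, so under a true null each 5% tail contributes
#' 5% of models, 10% in total. With `paired_null = TRUE` the tail
#' probabilities come from the exact paired null of
#' [auroc_pvalue_paired()], the calibrated reference for within-pair
#' transformed data; otherwise from the Mann-Whitney U null of
#' [auroc_pvalue()].
#'
#' @param x Numeric matrix (samples x variables), already quantitation
#'   filtered and, for the paired analysis, within-pair transformed.
#' @param pair Pair id per row.
#' @param labels Two-level class labels per row.
#' @param rank 0-based lexicographic rank of the training-pair subset.
#' @param n_train_pairs Number of training pairs.
#' @param n_components PLS components (default 2).
#' @param paired_null Use the exact paired AUROC null (default `TRUE`;
#'   appropriate iff `x` is within-pair transformed).
#' @param alpha Per-tail significance level (default 0.05).
#' @return A list of class `partition_model`: `rank`, `auroc`, `p_value`,
#'   `p_lower`, `p_upper`, `significant`, `better`, `worse`, `vip`,
#'   `n_train_pairs`, `n_test_pairs`.
#' @export
evaluate_partition <- function(x, pair, labels, rank, n_train_pairs = 22L,
                               n_components = 2L, paired_null = TRUE,
                               alpha = 0.05) {
  x <- as.matrix(x)
  pair <- as.character(pair)
  pairs <- unique(pair)
  n_pairs <- length(pairs)
  train_pairs <- pairs[unrank_combination(rank, n_pairs, n_train_pairs)]
  in_train <- pair %in% train_pairs
  fit <- plsda(x[in_train, , drop = FALSE],
               as.character(labels)[in_train],
               n_components = n_components, scale = TRUE)
  scores <- predict(fit, x[!in_train, , drop = FALSE])
  test_labels <- as.character(labels)[!in_train]
  a <- auroc(scores, test_labels)
  n_test_pairs <- n_pairs - n_train_pairs
  if (paired_null) {
    p_lower <- auroc_pvalue_paired(a, n_test_pairs, alternative = "less")
    p_upper <- auroc_pvalue_paired(a, n_test_pairs, alternative = "greater")
  } else {
    pos <- as_binary_labels(test_labels)
    p_lower <- auroc_pvalue(a, sum(pos), sum(!pos), alternative = "less")
    p_upper <- auroc_pvalue(a, sum(pos), sum(!pos), alternative = "greater")
  }
  p <- min(p_lower, p_upper)
  structure(list(rank = rank, auroc = a, p_value = p,
                 p_lower = p_lower, p_upper = p_upper,
                 significant = p <= alpha,
                 better = p_upper <= alpha, worse = p_lower <= alpha,
                 vip = fit$vip, n_train_pairs = n_train_pairs,
                 n_test_pairs = n_test_pairs),
            class = "partition_model")
}

#' @export
print.partition_model <- function(x, ...) {
  cat(sprintf("Partition %s: AUROC %.3f, p %.4f (%s)\n",
              format(x$rank, scientific = FALSE), x$auroc, x$p_value,
              if (x$better) "significantly better than the mean model"
              else if (x$worse) "significantly worse than the mean model"
              else "indistinguishable from the mean model"))
  invisible(x)
}

#' Summarize a stream of per-partition results and apply the decision rule
#'
#' Aggregates per-model AUROCs and tail probabilities into the distribution
#' summary and applies the selection rule: variable selection is performed
#' only when the median AUROC is at least `auroc_cutoff` and the median
#' p-value at most `p_cutoff`; in that case the variables whose median VIP
#' across models exceeds `vip_cutoff` are selected, otherwise the selection
#' is empty.
#'
#' @param results data.frame with columns `rank`, `auroc`, `p_value`,
#'   `better`, `worse` (one row per evaluated model).
#' @param vip Matrix of VIP values, models x variables (may be `NULL`, in
#'   which case a positive decision returns no variable names).
#' @param alpha Per-tail significance level used for the significant
#'   fractions.
#' @param auroc_cutoff,p_cutoff Median cutoffs of the decision rule
#'   (defaults 0.8 and 0.05).
#' @param vip_cutoff VIP threshold for selection (default 1).
#' @return An object of class `validation_summary`.
#' @export
summarize_validation <- function(results, vip = NULL, alpha = 0.05,
                                 auroc_cutoff = 0.8, p_cutoff = 0.05,
                                 vip_cutoff = 1) {
  stopifnot(all(c("auroc", "p_value", "better", "worse") %in%
                  names(results)))
  n <- nrow(results)
  median_auroc <- stats::median(results$auroc)
  median_p <- stats::median(results$p_value)
  decision <- median_auroc >= auroc_cutoff && median_p <= p_cutoff
  median_vip <- if (!is.null(vip)) apply(vip, 2, stats::median) else NULL
  selected <- if (decision && !is.null(median_vip))
    names(median_vip)[median_vip > vip_cutoff] else character(0)
  structure(list(n_models = n,
                 mean_auroc = mean(results$auroc),
                 median_auroc = median_auroc,
                 median_p = median_p,
                 fraction_significant = mean(results$better | results$worse),
                 fraction_significantly_better = mean(results$better),
                 fraction_significantly_worse = mean(results$worse),
                 alpha = alpha, auroc_cutoff = auroc_cutoff,
                 p_cutoff = p_cutoff, vip_cutoff = vip_cutoff,
                 decision = decision, selected_variables = selected,
                 median_vip = median_vip, results = results),
            class = "validation_summary")
}

#' Run the partition-validation sweep
#'
#' Evaluates a PLS-DA model on every partition of a [partition_plan()]:
#' for each sampled rank the matched pairs are split into training and test
#' sets, scaling and model fit use the training block only, and the test
#' block yields an AUROC with its tail probability against the mean model.
#' With `paired = TRUE` (default) the multilevel within-pair transform is
#' applied to the matrix first and significance is assessed against the
#' exact paired AUROC null; with `paired = FALSE` the plain analysis and the
#' Mann-Whitney null are used.
#'
#' @param x Numeric matrix or [conc_matrix], samples x variables
#'   (quantitation-filtered).
#' @param pair Pair id per sample.
#' @param labels Two-level group labels per sample.
#' @param plan A [partition_plan()].
#' @param n_components PLS components per model (default 2).
#' @param paired Apply the within-pair transform (default `TRUE`).
#' @param alpha Per-tail significance level (default 0.05).
#' @param auroc_cutoff,p_cutoff,vip_cutoff Decision-rule parameters.
#' @param stream Optional path; when given, one JSON line per model (rank,
#'   auroc, p_value, vip) is appended as results are produced.
#' @param keep_vip Retain the models x variables VIP matrix in the result
#'   (default `TRUE`; needed for variable selection).
#' @return A `validation_summary` (see [summarize_validation()]) whose
#'   `results` element holds the per-model stream.
#' @examples
#' sim <- generate_cohort(cohort_config(n_pairs = 8, seed = 1))
#' filt <- filter_metabolites(sim$matrix)
#' plan <- partition_plan(n_pairs = 8, n_train_pairs = 5, max_models = 20)
#' v <- run_validation(filt$matrix, sim$cohort$pair_id, sim$cohort$group,
#'                     plan, n_components = 2)
#' v
#' @export
run_validation <- function(x, pair, labels, plan, n_components = 2L,
                           paired = TRUE, alpha = 0.05, auroc_cutoff = 0.8,
                           p_cutoff = 0.05, vip_cutoff = 1, stream = NULL,
                           keep_vip = TRUE) {
  if (inherits(x, "conc_matrix")) x <- x$values
  x <- as.matrix(x)
  stopifnot(inherits(plan, "partition_plan"))
  pair <- as.character(pair)
  if (length(unique(pair)) != plan$n_pairs)
    stop("plan expects ", plan$n_pairs, " pairs, data has ",
         length(unique(pair)))
  if (paired) x <- within_pair_transform(x, pair)
  con <- NULL
  if (!is.null(stream)) {
    con <- file(stream, open = "wt")
    on.exit(close(con), add = TRUE)
  }
  m <- length(plan$ranks)
  res <- data.frame(rank = plan$ranks, auroc = numeric(m),
                    p_value = numeric(m), better = logical(m),
                    worse = logical(m))
  vip_mat <- if (keep_vip) matrix(NA_real_, m, ncol(x),
                                  dimnames = list(NULL, colnames(x)))
             else NULL
  for (i in seq_len(m)) {
    r <- evaluate_partition(x, pair, labels, plan$ranks[i],
                            n_train_pairs = plan$n_train_pairs,
                            n_components = n_components,
                            paired_null = paired, alpha = alpha)
    res$auroc[i] <- r$auroc
    res$p_value[i] <- r$p_value
    res$better[i] <- r$better
    res$worse[i] <- r$worse
    if (keep_vip) vip_mat[i, names(r$vip)] <- r$vip
    if (!is.null(con))
      writeLines(jsonlite::toJSON(list(rank = r$rank, auroc = r$auroc,
                                       p_value = r$p_value,
                                       vip = as.list(r$vip)),
                                  auto_unbox = TRUE, digits = NA), con)
  }
  out <- summarize_validation(res, vip = vip_mat, alpha = alpha,
                              auroc_cutoff = auroc_cutoff,
                              p_cutoff = p_cutoff, vip_cutoff = vip_cutoff)
  out$plan <- plan
  out$paired <- paired
  out$n_components <- n_components
  out
}

#' @export
print.validation_summary <- function(x, ...) {
  cat("Partition validation:", format(x$n_models, big.mark = ","),
      "models\n")
  cat(sprintf("  AUROC: mean %.3f, median %.3f;  median p %.3f\n",
              x$mean_auroc, x$median_auroc, x$median_p))
  cat(sprintf("  significantly different from the mean model: %.1f%% (better %.1f%%, worse %.1f%%) at per-tail alpha %.2f\n",
              100 * x$fraction_significant,
              100 * x$fraction_significantly_better,
              100 * x$fraction_significantly_worse, x$alpha))
  if (x$decision) {
    cat(sprintf("  decision: SATISFACTORY (median AUROC >= %.2f and median p <= %.2f)\n",
                x$auroc_cutoff, x$p_cutoff))
    cat("  selected variables (median VIP >", x$vip_cutoff, "):",
        if (length(x$selected_variables))
          paste(x$selected_variables, collapse = ", ") else "<none>", "\n")
  } else {
    cat(sprintf("  decision: not satisfactory (need median AUROC >= %.2f and median p <= %.2f); no variable selection\n",
                x$auroc_cutoff, x$p_cutoff))
  }
  invisible(x)
}

#' @export
summary.validation_summary <- function(object, ...) {
  print(object)
  cat("AUROC quartiles:\n")
  print(round(stats::quantile(object$results$auroc), 3))
  invisible(object)
}

#' @export
plot.validation_summary <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::hist(x$results$auroc, breaks = 30, main = "Test-set AUROC",
                 xlab = "AUROC", col = "grey80")
  graphics::abline(v = x$median_auroc, lwd = 2)
  graphics::hist(x$results$p_value, breaks = 30,
                 main = "Mean-model tail probability", xlab = "p-value",
                 col = "grey80")
  graphics::abline(v = x$alpha, lwd = 2, lty = 2)
  invisible(x)
}

#' Export AUROC and p-value histograms as TSV tables
#'
#' @param x A `validation_summary`.
#' @param auroc_path,p_path Output TSV paths (bin edges and counts).
#' @param n_bins Number of histogram bins (default 40).
#' @return Invisibly, a list with the two histogram data.frames.
#' @export
write_validation_histograms <- function(x, auroc_path, p_path,
                                        n_bins = 40L) {
  stopifnot(inherits(x, "validation_summary"))
  tsv <- function(values, lo, hi, path) {
    edges <- seq(lo, hi, length.out = n_bins + 1L)
    counts <- graphics::hist(values, breaks = edges, plot = FALSE)$counts
    df <- data.frame(bin_low = edges[-length(edges)], bin_high = edges[-1],
                     count = counts)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    df
  }
  invisible(list(
    auroc = tsv(x$results$auroc, 0, 1, auroc_path),
    p_value = tsv(x$results$p_value, 0, 1, p_path)))
}
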