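#' Multilevel within-pair decomposition
#'
#' Replaces each measurement by its deviation from the mean of its matched
#' pair, the multilevel transform that turns PCA/PLS-DA on a matched design
#' into an analysis of within-pair differences. For a two-member pair with
#' values `(a, b)` the transformed values are `((a - b)/2, (b - a)/2)`, so
#' per-pair column means are exactly zero.
#'
#' @param x Numeric matrix (samples x variables) or [conc_matrix].
#' @param pair Pair identifier per row; every pair must be complete (exactly
#'   two rows).
#' @return Numeric matrix of within-pair deviations, same shape as the
#'   input.
#' @examples
#' x <- matrix(c(1, 3, 10, 14), 2, 2)
#' within_pair_transform(x, c("p1", "p1"))
#' @export
within_pair_transform <- function(x, pair) {
  if (inherits(x, "conc_matrix")) x <- x$values
  x <- as.matrix(x)
  if (nrow(x) != length(pair)) stop("one pair id per row required")
  sizes <- table(pair)
  if (any(sizes != 2L))
    stop("incomplete pair(s): ",
         paste(names(sizes)[sizes != 2L], collapse = ", "))
  pm <- rowsum(x, pair, reorder = FALSE) / 2
  out <- x - pm[match(pair, rownames(pm)), , drop = FALSE]
  dimnames(out) <- dimnames(x)
  out
}

#' Unit-variance (auto) scaling fitted on training data
#'
#' Centers and scales every column of the training block to mean 0 and
#' standard deviation 1 (n - 1 denominator), and applies the identical
#' transform -- never a refit -- to an optional test block. Columns with
#' zero training variance are dropped with a warning from both blocks.
#'
#' @param train Numeric matrix, at least two rows.
#' @param test Optional numeric matrix with the same columns.
#' @return A list of class `autoscaled`: `train`, `test` (or `NULL`),
#'   `center`, `scale`, `kept` (column index retained).
#' @examples
#' autoscale(matrix(1:3, 3, 1))$train
#' @export
autoscale <- function(train, test = NULL) {
  train <- as.matrix(train)
  if (nrow(train) < 2L) stop("at least 2 training rows are required")
  ctr <- colMeans(train)
  scl <- apply(train, 2, stats::sd)
  kept <- which(scl > 0)
  if (length(kept) < ncol(train))
    warning(ncol(train) - length(kept),
            " zero-variance column(s) dropped before scaling")
  if (length(kept) == 0L) stop("no column with positive training variance")
  tr <- scale(train[, kept, drop = FALSE], center = ctr[kept],
              scale = scl[kept])
  attr(tr, "scaled:center") <- NULL; attr(tr, "scaled:scale") <- NULL
  te <- NULL
  if (!is.null(test)) {
    test <- as.matrix(test)
    if (ncol(test) != ncol(train)) stop("test columns must match train")
    te <- scale(test[, kept, drop = FALSE], center = ctr[kept],
                scale = scl[kept])
    attr(te, "scaled:center") <- NULL; attr(te, "scaled:scale") <- NULL
  }
  structure(list(train = tr, test = te, center = ctr[kept],
                 scale = scl[kept], kept = kept),
            class = "autoscaled")
}

# enforce a deterministic sign: largest-magnitude element of each loading
# column is positive
fix_signs <- function(scores, loadings) {
  for (a in seq_len(ncol(loadings))) {
    k <- which.max(abs(loadings[, a]))
    if (loadings[k, a] < 0) {
      loadings[, a] <- -loadings[, a]
      scores[, a] <- -scores[, a]
    }
  }
  list(scores = scores, loadings = loadings)
}

#' Principal component analysis by NIPALS
#'
#' Computes principal components one at a time by the NIPALS alternating
#' projection algorithm. Loadings are orthonormal, score columns orthogonal,
#' and explained-variance fractions non-increasing. The sign of each
#' component is fixed so its largest-magnitude loading is positive.
#'
#' @param x Numeric matrix; centered internally unless `center = FALSE`.
#' @param n_components Number of components, at most `min(nrow - 1, ncol)`.
#' @param center Center columns before decomposition (default `TRUE`).
#' @param tol Convergence tolerance: iteration stops when the relative
#'   change of the score vector, `||t_new - t|| / ||t_new||`, falls below
#'   `tol`.
#' @param max_iter Maximum NIPALS iterations per component.
#' @return An object of class `nipals_pca`: `scores` (n x a), `loadings`
#'   (p x a), `explained_variance` (fraction per component), `center`,
#'   `total_ss`.
#' @examples
#' fit <- pca_nipals(matrix(rnorm(60), 10, 6), 2)
#' fit$explained_variance
#' @export
pca_nipals <- function(x, n_components = 2, center = TRUE,
                       tol = 1e-12, max_iter = 1000L) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n_components > min(n - 1L, p))
    stop("'n_components' must be <= min(nrow - 1, ncol)")
  ctr <- if (center) colMeans(x) else rep(0, p)
  X <- sweep(x, 2, ctr)
  total_ss <- sum(X^2)
  scores <- matrix(0, n, n_components)
  loadings <- matrix(0, p, n_components)
  for (a in seq_len(n_components)) {
    t_vec <- X[, which.max(colSums(X^2))]
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      p_vec <- drop(crossprod(X, t_vec)) / sum(t_vec^2)
      p_vec <- p_vec / sqrt(sum(p_vec^2))
      t_new <- drop(X %*% p_vec)
      if (sum((t_new - t_vec)^2) <= tol^2 * sum(t_new^2)) {
        t_vec <- t_new; converged <- TRUE; break
      }
      t_vec <- t_new
    }
    if (!converged)
      stop("NIPALS failed to converge for component ", a, " after ",
           max_iter, " iterations")
    scores[, a] <- t_vec
    loadings[, a] <- p_vec
    X <- X - tcrossprod(t_vec, p_vec)
  }
  sf <- fix_signs(scores, loadings)
  dimnames(sf$loadings) <- list(colnames(x), paste0("PC", seq_len(n_components)))
  dimnames(sf$scores) <- list(rownames(x), paste0("PC", seq_len(n_components)))
  structure(list(scores = sf$scores, loadings = sf$loadings,
                 explained_variance = colSums(sf$scores^2) / total_ss,
                 center = ctr, total_ss = total_ss),
            class = "nipals_pca")
}

#' @export
print.nipals_pca <- function(x, ...) {
  cat("NIPALS PCA:", nrow(x$scores), "samples,", ncol(x$scores),
      "components\n  explained variance:",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "),
      "\n")
  invisible(x)
}

#' Hotelling T-squared outlier screening on PCA scores
#'
#' Computes the Hotelling T-squared statistic of every sample from the
#' score variances of a fitted PCA model and flags samples beyond the
#' F-distribution-based control limit, the standard outlier screen on a
#' scores plot.
#'
#' @param model A `nipals_pca` fit with at least 2 components on at least 3
#'   samples.
#' @param alpha Confidence level of the control limit (default 0.95).
#' @return A list: `t2` (statistic per sample), `limit`, `outlier` (logical
#'   flags).
#' @examples
#' fit <- pca_nipals(matrix(rnorm(100), 20, 5), 2)
#' hotelling_t2(fit)$limit
#' @export
hotelling_t2 <- function(model, alpha = 0.95) {
  stopifnot(inherits(model, "nipals_pca"))
  Tm <- model$scores
  n <- nrow(Tm); a <- ncol(Tm)
  if (a < 2L) stop("at least 2 components are required")
  if (n < 3L) stop("at least 3 samples are required")
  v <- apply(Tm, 2, stats::var)
  if (any(v <= 0)) stop("degenerate (zero-variance) score column")
  t2 <- rowSums(sweep(Tm^2, 2, v, `/`))
  limit <- a * (n - 1) / (n - a) * stats::qf(alpha, a, n - a)
  list(t2 = t2, limit = limit, outlier = t2 > limit)
}
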