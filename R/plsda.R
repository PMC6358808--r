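#' Partial least squares discriminant analysis (NIPALS PLS1)
#'
#' Fits a PLS regression of a dummy-coded binary class label on the
#' predictor matrix by the NIPALS PLS1 algorithm: per component the weight
#' vector is the (normalized) covariance direction `X'y`, scores are `X w`,
#' and both blocks are deflated by the x-loadings. Predictors are
#' unit-variance scaled by default using statistics fitted on the supplied
#' (training) data only; [predict.plsda()] re-applies the stored transform
#' to new samples, so no test information ever enters the fit.
#'
#' @param x Numeric matrix, samples x variables.
#' @param y Binary class labels: logical, 0/1 numeric, or a two-level
#'   factor/character vector. The level sorted last is coded 1 ("positive").
#' @param n_components Number of latent components (default 2).
#' @param scale Unit-variance scale the columns (default `TRUE`); centering
#'   is always applied. Zero-variance columns are dropped with a warning.
#' @return An object of class `plsda` with elements `weights` (p x a, unit
#'   norm columns), `x_loadings`, `scores` (orthogonal columns),
#'   `y_loadings`, `coefficients` (regression vector on the scaled space),
#'   `ssy` (explained y sum of squares per component), `vip`, `center`,
#'   `scale`, `y_mean`, `levels`, `fitted_values`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(80), 20, 4)
#' y <- rep(c("ctrl", "case"), 10)
#' fit <- plsda(x, y, n_components = 2)
#' fit
#' @seealso [predict.plsda()], [vip()]
#' @export
plsda <- function(x, y, n_components = 2, scale = TRUE) {
  x <- as.matrix(x)
  if (is.factor(y) || is.character(y)) {
    lev <- sort(unique(as.character(y)))
    if (length(lev) != 2L) stop("'y' must have exactly two classes")
    yb <- as.numeric(as.character(y) == lev[2])
  } else {
    yb <- as.numeric(y)
    if (!all(yb %in% c(0, 1))) stop("numeric 'y' must be coded 0/1")
    lev <- c("0", "1")
    if (length(unique(yb)) != 2L) stop("'y' must have exactly two classes")
  }
  if (nrow(x) != length(yb)) stop("one label per row of 'x' required")
  if (n_components < 1L) stop("'n_components' must be >= 1")

  ctr <- colMeans(x)
  scl <- if (scale) apply(x, 2, stats::sd) else rep(1, ncol(x))
  kept <- which(scl > 0)
  if (length(kept) < ncol(x))
    warning(ncol(x) - length(kept), " zero-variance column(s) dropped")
  X <- sweep(sweep(x[, kept, drop = FALSE], 2, ctr[kept]), 2, scl[kept], `/`)
  y_mean <- mean(yb)
  yr <- yb - y_mean

  p <- ncol(X)
  a_max <- min(n_components, nrow(X) - 1L, p)
  W <- P <- matrix(0, p, a_max)
  Tm <- matrix(0, nrow(X), a_max)
  q <- ssy <- numeric(a_max)
  Xd <- X; yd <- yr
  for (a in seq_len(a_max)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps^0.5) {
      a_max <- a - 1L
      if (a_max == 0L) stop("X carries no covariance with y")
      W <- W[, seq_len(a_max), drop = FALSE]
      P <- P[, seq_len(a_max), drop = FALSE]
      Tm <- Tm[, seq_len(a_max), drop = FALSE]
      q <- q[seq_len(a_max)]; ssy <- ssy[seq_len(a_max)]
      break
    }
    w <- w / nw
    t_vec <- drop(Xd %*% w)
    tt <- sum(t_vec^2)
    p_vec <- drop(crossprod(Xd, t_vec)) / tt
    qa <- sum(yd * t_vec) / tt
    Xd <- Xd - tcrossprod(t_vec, p_vec)
    yd <- yd - t_vec * qa
    W[, a] <- w; P[, a] <- p_vec; Tm[, a] <- t_vec
    q[a] <- qa; ssy[a] <- qa^2 * tt
  }
  B <- drop(W %*% solve(crossprod(P, W), q))
  fitted <- y_mean + drop(X %*% B)
  vars <- colnames(x)[kept]
  if (is.null(vars)) vars <- paste0("V", kept)
  rownames(W) <- rownames(P) <- names(B) <- vars
  obj <- structure(list(weights = W, x_loadings = P, scores = Tm,
                        y_loadings = q, coefficients = B, ssy = ssy,
                        n_components = a_max, center = ctr[kept],
                        scale = scl[kept], kept = kept, y_mean = y_mean,
                        levels = lev, variables = vars,
                        fitted_values = fitted, y = yb,
                        scaled = scale),
                   class = "plsda")
  obj$vip <- vip(obj)
  obj
}

#' Predict continuous discriminant scores for new samples
#'
#' Applies the centering/scaling stored in the fit and returns the
#' continuous predicted response on the dummy-code scale (values near 1
#' point to the positive class, near 0 to the reference class). With
#' `type = "class"` the score is thresholded at the midpoint 0.5.
#'
#' @param object A [plsda] fit.
#' @param newdata Numeric matrix with the same variables as the training
#'   data.
#' @param type `"response"` (continuous score, default) or `"class"`.
#' @param ... Unused.
#' @return Numeric vector of scores, or a character vector of class labels.
#' @export
predict.plsda <- function(object, newdata,
                          type = c("response", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) == length(object$kept) + 0L &&
      !is.null(colnames(newdata)) &&
      all(object$variables %in% colnames(newdata))) {
    newdata <- newdata[, object$variables, drop = FALSE]
  } else if (ncol(newdata) >= max(object$kept)) {
    newdata <- newdata[, object$kept, drop = FALSE]
  } else {
    stop("'newdata' has ", ncol(newdata),
         " columns; the model was trained on variables up to index ",
         max(object$kept))
  }
  Z <- sweep(sweep(newdata, 2, object$center), 2, object$scale, `/`)
  score <- object$y_mean + drop(Z %*% object$coefficients)
  if (type == "class")
    ifelse(score > 0.5, object$levels[2], object$levels[1])
  else score
}

#' Variable importance in projection
#'
#' VIP summarizes the contribution of each variable across the latent
#' components, weighting squared (unit-norm) weights by the y-variance each
#' component explains:
#' `VIP_j = sqrt(p * sum_a ssy_a w_aj^2 / sum_a ssy_a)`. Mean squared VIP is
#' 1 by construction; variables above 1 are conventionally called important
#' for the discrimination.
#'
#' @param object A fitted model with per-component explained y-variance.
#' @param ... Passed to methods.
#' @return Numeric vector of VIP values, one per variable.
#' @export
vip <- function(object, ...) UseMethod("vip")

#' @rdname vip
#' @export
vip.plsda <- function(object, ...) {
  ssy <- object$ssy
  if (sum(ssy) <= 0) stop("total explained y-variance is zero")
  W2 <- object$weights^2
  v <- sqrt(nrow(W2) * drop(W2 %*% ssy) / sum(ssy))
  names(v) <- object$variables
  v
}

#' @export
coef.plsda <- function(object, ...) object$coefficients

#' @export
fitted.plsda <- function(object, ...) object$fitted_values

#' @export
residuals.plsda <- function(object, ...) object$y - object$fitted_values

#' @export
print.plsda <- function(x, ...) {
  cat("PLS-DA (NIPALS PLS1):", length(x$y), "samples,",
      length(x$variables), "variables,", x$n_components, "component(s)\n")
  cat("  classes:", x$levels[1], "(0) vs", x$levels[2], "(1)\n")
  cat("  explained y-variance per component:",
      paste(sprintf("%.1f%%",
                    100 * x$ssy / sum((x$y - mean(x$y))^2)),
            collapse = ", "), "\n")
  cat("  variables with VIP > 1:", sum(x$vip > 1), "\n")
  invisible(x)
}

#' Serialize a fitted PLS-DA model to JSON
#'
#' Writes weights, loadings, scores, y-loadings, regression coefficients,
#' VIP and the stored centering/scaling statistics, so a fit can be archived
#' or applied elsewhere.
#'
#' @param object A [plsda] fit.
#' @param path Output JSON path.
#' @return Invisibly, `object`.
#' @export
write_plsda_json <- function(object, path) {
  stopifnot(inherits(object, "plsda"))
  payload <- list(
    n_components = object$n_components,
    levels = object$levels,
    variables = object$variables,
    weights = unname(split(object$weights, col(object$weights))),
    x_loadings = unname(split(object$x_loadings, col(object$x_loadings))),
    scores = unname(split(object$scores, col(object$scores))),
    y_loadings = object$y_loadings,
    coefficients = unname(object$coefficients),
    ssy = object$ssy,
    vip = unname(object$vip),
    center = unname(object$center),
    scale = unname(object$scale),
    y_mean = object$y_mean)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(object)
}

#' @export
summary.plsda <- function(object, ...) {
  print(object)
  top <- sort(object$vip, decreasing = TRUE)
  cat("Top VIP:\n")
  print(round(utils::head(top, 10), 3))
  invisible(object)
}
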