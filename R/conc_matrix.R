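#' Concentration matrix with quantitation limits
#'
#' Container for a samples-by-metabolites concentration matrix (umol/L)
#' together with per-metabolite annotation (name, biochemical family, lower
#' and upper limits of quantitation) and a logical censor-flag matrix of the
#' same shape marking measurements outside the quantitation limits. Values
#' are kept as reported even when flagged: the quantitation filter consumes
#' the flags, not the values.
#'
#' @param values Numeric matrix, samples in rows, metabolites in columns;
#'   column names must match `annotations$name`.
#' @param annotations data.frame with columns `name`, `family`, `lloq`,
#'   `uloq` (one row per column of `values`, `lloq < uloq`).
#' @param censored Optional logical matrix of the same shape as `values`;
#'   recomputed from the limits when `NULL`.
#' @return An object of class `conc_matrix`: a list with elements `values`,
#'   `annotations`, `censored`.
#' @examples
#' v <- matrix(c(1, 2, 3, 4), 2, 2, dimnames = list(NULL, c("a", "b")))
#' ann <- data.frame(name = c("a", "b"), family = "amino acids",
#'                   lloq = 0.5, uloq = 10)
#' m <- conc_matrix(v, ann)
#' m$censored
#' @export
conc_matrix <- function(values, annotations, censored = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be a numeric matrix")
  req <- c("name", "family", "lloq", "uloq")
  if (!all(req %in% names(annotations)))
    stop("'annotations' needs columns ", paste(req, collapse = ", "))
  if (nrow(annotations) != ncol(values))
    stop("one annotation row per metabolite column required")
  if (is.null(colnames(values))) colnames(values) <- annotations$name
  if (!identical(colnames(values), annotations$name))
    stop("column names of 'values' must match annotations$name")
  bad <- which(!(annotations$lloq < annotations$uloq))
  if (length(bad))
    stop("LLOQ must be below ULOQ; offending metabolite(s): ",
         paste(annotations$name[bad], collapse = ", "))
  x <- structure(list(values = values,
                      annotations = as.data.frame(annotations,
                                                  stringsAsFactors = FALSE),
                      censored = NULL),
                 class = "conc_matrix")
  x$censored <- if (is.null(censored)) censor_flags(x) else {
    censored <- as.matrix(censored)
    if (!identical(dim(censored), dim(values)))
      stop("'censored' must have the same shape as 'values'")
    storage.mode(censored) <- "logical"
    dimnames(censored) <- dimnames(values)
    censored
  }
  x
}

# censor flag is TRUE iff the value lies strictly below LLOQ or strictly
# above ULOQ; missing values count as not measured accurately
censor_flags <- function(x) {
  ann <- x$annotations
  if (anyNA(ann$lloq) || anyNA(ann$uloq)) {
    bad <- ann$name[is.na(ann$lloq) | is.na(ann$uloq)]
    stop("missing quantitation limits for: ", paste(bad, collapse = ", "))
  }
  below <- sweep(x$values, 2, ann$lloq, `<`)
  above <- sweep(x$values, 2, ann$uloq, `>`)
  flags <- below | above
  flags[is.na(flags)] <- TRUE
  dimnames(flags) <- dimnames(x$values)
  flags
}

#' @export
print.conc_matrix <- function(x, ...) {
  cat("Concentration matrix:", nrow(x$values), "samples x",
      ncol(x$values), "metabolites (umol/L)\n")
  fam <- table(x$annotations$family)
  cat("  families:",
      paste(sprintf("%s (%d)", names(fam), fam), collapse = ", "), "\n")
  cat("  out-of-range cells:", sum(x$censored),
      sprintf("(%.1f%%)", 100 * mean(x$censored)), "\n")
  invisible(x)
}

#' @export
dim.conc_matrix <- function(x) dim(x$values)

#' Subset a concentration matrix by metabolite
#'
#' @param x A [conc_matrix].
#' @param keep Logical, integer or character index of metabolites to keep.
#' @return A [conc_matrix] restricted to the selected columns, order
#'   preserved.
#' @export
subset_metabolites <- function(x, keep) {
  stopifnot(inherits(x, "conc_matrix"))
  if (is.character(keep)) keep <- match(keep, x$annotations$name)
  conc_matrix(x$values[, keep, drop = FALSE],
              x$annotations[keep, , drop = FALSE],
              x$censored[, keep, drop = FALSE])
}
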