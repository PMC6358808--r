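#' Recompute out-of-range censor flags from quantitation limits
#'
#' Marks every measurement that is strictly below the metabolite's lower
#' limit of quantitation or strictly above its upper limit. A value exactly
#' at a limit is considered accurately measured. Missing values are flagged.
#' Concentration values themselves are never altered.
#'
#' @param x A [conc_matrix].
#' @return The same [conc_matrix] with its censor flags recomputed.
#' @examples
#' v <- matrix(c(0.4, 0.5, 1, 11), 2, 2, dimnames = list(NULL, c("a", "b")))
#' ann <- data.frame(name = c("a", "b"), family = "x", lloq = 0.5, uloq = 10)
#' flag_out_of_range(conc_matrix(v, ann))$censored
#' @export
flag_out_of_range <- function(x) {
  stopifnot(inherits(x, "conc_matrix"))
  x$censored <- censor_flags(x)
  x
}

#' Quantitation-accuracy filter
#'
#' Drops every metabolite whose fraction of out-of-range measurements
#' exceeds `max_fraction` (strictly more than 20% by default: a metabolite
#' with exactly 20% flagged values is kept). Returns the filtered matrix,
#' column order preserved, together with a per-metabolite retention report.
#'
#' @param x A [conc_matrix] with populated censor flags.
#' @param max_fraction Largest tolerated out-of-range fraction; default 0.20.
#' @return A list with elements
#'   \describe{
#'     \item{matrix}{the [conc_matrix] restricted to retained metabolites;}
#'     \item{report}{a `retention_report`: data.frame with columns `name`,
#'       `family`, `n_samples`, `n_out_of_range`, `out_of_range_fraction`,
#'       `retained`, plus attributes `n_input`, `n_retained`,
#'       `retained_fraction`.}
#'   }
#' @examples
#' sim <- generate_cohort(cohort_config(seed = 1))
#' filt <- filter_metabolites(sim$matrix)
#' attr(filt$report, "n_retained")
#' @export
filter_metabolites <- function(x, max_fraction = 0.20) {
  stopifnot(inherits(x, "conc_matrix"))
  if (!is.numeric(max_fraction) || max_fraction < 0 || max_fraction >= 1)
    stop("'max_fraction' must lie in [0, 1)")
  n <- nrow(x$values)
  n_oor <- colSums(x$censored)
  frac <- n_oor / n
  retained <- frac <= max_fraction
  if (!any(retained))
    stop("no metabolite passes the quantitation filter at max_fraction = ",
         max_fraction)
  report <- data.frame(name = x$annotations$name,
                       family = x$annotations$family,
                       n_samples = n,
                       n_out_of_range = as.integer(n_oor),
                       out_of_range_fraction = frac,
                       retained = retained,
                       stringsAsFactors = FALSE)
  rownames(report) <- NULL
  attr(report, "n_input") <- ncol(x$values)
  attr(report, "n_retained") <- sum(retained)
  attr(report, "retained_fraction") <- sum(retained) / ncol(x$values)
  attr(report, "max_fraction") <- max_fraction
  class(report) <- c("retention_report", "data.frame")
  list(matrix = subset_metabolites(x, retained), report = report)
}

#' @export
print.retention_report <- function(x, ...) {
  n_in <- attr(x, "n_input"); n_ret <- attr(x, "n_retained")
  cat(sprintf("Quantitation filter (> %.0f%% out-of-range dropped): %d of %d metabolites retained (%.1f%%)\n",
              100 * attr(x, "max_fraction"), n_ret, n_in,
              100 * attr(x, "retained_fraction")))
  fam <- stats::aggregate(retained ~ family, data = x, FUN = sum)
  tot <- stats::aggregate(retained ~ family,
                          data = transform(x, retained = TRUE), FUN = sum)
  for (i in seq_len(nrow(fam)))
    cat(sprintf("  %-26s %3d / %3d\n", fam$family[i], fam$retained[i],
                tot$retained[i]))
  invisible(x)
}
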