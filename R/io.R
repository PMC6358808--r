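#' Write a concentration matrix and its side tables to CSV
#'
#' Writes the wide concentration CSV (first column `sample_id`, one column
#' per metabolite), the metabolite annotation CSV (`name`, `family`, `lloq`,
#' `uloq`) and a censor-flag CSV of the same shape as the values. Floats are
#' serialized at full precision.
#'
#' @param x A [conc_matrix].
#' @param values_path,annotations_path Output CSV paths.
#' @param censor_path Optional censor-flag CSV path.
#' @return Invisibly, `x`.
#' @export
write_concentrations <- function(x, values_path, annotations_path,
                                 censor_path = NULL) {
  stopifnot(inherits(x, "conc_matrix"))
  df <- data.frame(sample_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, values_path, row.names = FALSE)
  utils::write.csv(x$annotations, annotations_path, row.names = FALSE)
  if (!is.null(censor_path)) {
    cf <- data.frame(sample_id = rownames(x$values), x$censored,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.csv(cf, censor_path, row.names = FALSE)
  }
  invisible(x)
}

#' Read a concentration matrix from CSV
#'
#' Parses the wide-CSV dialect written by [write_concentrations()]. Parse
#' problems are reported with the offending row and column so malformed
#' user data fails loudly.
#'
#' @param values_path Wide CSV, first column `sample_id`.
#' @param annotations_path Annotation CSV with `name`, `family`, `lloq`,
#'   `uloq`.
#' @param censor_path Optional censor-flag CSV; recomputed from the limits
#'   when absent.
#' @return A [conc_matrix].
#' @export
read_concentrations <- function(values_path, annotations_path,
                                censor_path = NULL) {
  raw <- utils::read.csv(values_path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (ncol(raw) < 2L || names(raw)[1] != "sample_id")
    stop("malformed concentration CSV '", values_path,
         "': first column must be 'sample_id'")
  for (j in 2:ncol(raw)) {
    v <- raw[[j]]
    if (is.character(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & nzchar(v))
      if (length(bad))
        stop("malformed concentration CSV '", values_path, "': row ",
             bad[1] + 1L, ", column '", names(raw)[j],
             "' is not numeric (value '", v[bad[1]], "')")
      raw[[j]] <- num
    }
  }
  values <- as.matrix(raw[, -1, drop = FALSE])
  rownames(values) <- raw$sample_id
  ann <- utils::read.csv(annotations_path, stringsAsFactors = FALSE)
  censored <- NULL
  if (!is.null(censor_path)) {
    cf <- utils::read.csv(censor_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
    censored <- as.matrix(cf[, -1, drop = FALSE])
    storage.mode(censored) <- "logical"
  }
  conc_matrix(values, ann, censored)
}

#' Write and read a cohort manifest CSV
#'
#' @param cohort Manifest data.frame as produced by [generate_cohort()].
#' @param path CSV path.
#' @return Invisibly the manifest (write) or the manifest (read).
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(cohort)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("subject_id", "pair_id", "group")
  if (!all(req %in% names(cohort)))
    stop("malformed cohort CSV '", path, "': need columns ",
         paste(req, collapse = ", "))
  cohort
}

#' Write univariate results or a retention report as TSV
#'
#' @param x A `univariate_results` or `retention_report` data.frame.
#' @param path Output TSV path.
#' @return Invisibly, `x`.
#' @export
write_tsv_report <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' Read a run configuration from JSON or YAML
#'
#' The file extension selects the parser (`.json` vs `.yml`/`.yaml`).
#'
#' @param path Configuration file path.
#' @return A named list of configuration values.
#' @export
read_run_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                yml = ,
                yaml = yaml::read_yaml(path),
                stop("unsupported config format '.", ext,
                     "' (use .json, .yml or .yaml)"))
  cfg
}
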