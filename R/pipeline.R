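#' Assemble a pipeline run configuration
#'
#' Collects every stage parameter into one validated list. `mode` selects
#' the data source: `"synthetic-effect"` and `"synthetic-null"` generate a
#' cohort (seed required), `"user-data"` reads the three CSVs
#' (`concentrations`, `annotations`, `manifest`, optionally `censor_flags`).
#'
#' @param mode One of `"synthetic-effect"`, `"synthetic-null"`,
#'   `"user-data"`.
#' @param out_dir Output directory for all artifacts.
#' @param seed Integer seed (mandatory in synthetic modes).
#' @param n_pairs Pairs in synthetic modes (default 32).
#' @param max_fraction Quantitation-filter threshold (default 0.20).
#' @param n_components PLS components (default 2).
#' @param train_pairs Training pairs per partition (default 22).
#' @param step,offset Systematic sampling parameters (defaults 310, 0).
#' @param max_models Cap on evaluated models (default 5000); set to `NULL`
#'   to honour `step` exactly (full sweep).
#' @param paired Run the paired (multilevel) analysis (default `TRUE`).
#' @param alpha,auroc_cutoff,p_cutoff,vip_cutoff Decision parameters.
#' @param concentrations,annotations,manifest,censor_flags Input CSV paths
#'   for `"user-data"` mode.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic-effect", "synthetic-null",
                                "user-data"),
                       out_dir, seed = NULL, n_pairs = 32L,
                       max_fraction = 0.20, n_components = 2L,
                       train_pairs = 22L, step = 310L, offset = 0L,
                       max_models = 5000L, paired = TRUE, alpha = 0.05,
                       auroc_cutoff = 0.8, p_cutoff = 0.05, vip_cutoff = 1,
                       concentrations = NULL, annotations = NULL,
                       manifest = NULL, censor_flags = NULL) {
  mode <- match.arg(mode)
  if (mode != "user-data" && is.null(seed))
    stop("'seed' is mandatory in synthetic modes")
  if (mode == "user-data" &&
      (is.null(concentrations) || is.null(annotations) || is.null(manifest)))
    stop("user-data mode needs 'concentrations', 'annotations' and 'manifest'")
  stopifnot(max_fraction >= 0, max_fraction < 1, alpha > 0, alpha < 1,
            auroc_cutoff > 0.5, auroc_cutoff <= 1, p_cutoff > 0,
            p_cutoff < 1, vip_cutoff > 0)
  structure(list(mode = mode, out_dir = out_dir, seed = seed,
                 n_pairs = as.integer(n_pairs),
                 max_fraction = max_fraction,
                 n_components = as.integer(n_components),
                 train_pairs = as.integer(train_pairs),
                 step = as.integer(step), offset = as.integer(offset),
                 max_models = if (is.null(max_models)) NULL
                              else as.integer(max_models),
                 paired = paired, alpha = alpha,
                 auroc_cutoff = auroc_cutoff, p_cutoff = p_cutoff,
                 vip_cutoff = vip_cutoff,
                 concentrations = concentrations, annotations = annotations,
                 manifest = manifest, censor_flags = censor_flags),
            class = "run_config")
}

pipeline_log <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), " ", ...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full analysis pipeline
#'
#' Executes generate/read -> quantitation filter -> paired univariate
#' statistics (metabolites and, in synthetic modes, routine biomarkers) ->
#' paired PCA with Hotelling T-squared screening -> partition-validated
#' PLS-DA, writing every intermediate artifact plus a machine-readable
#' (JSON) and human-readable (text) run report into `out_dir`.
#'
#' @param config A [run_config()] or the path of a JSON/YAML file holding
#'   its fields.
#' @return Invisibly, the run report as a list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- do.call(run_config,
                                              read_run_config(config))
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(config$out_dir, "run.log")
  logcon <- file(logfile, open = "wt")
  on.exit(close(logcon), add = TRUE)
  timings <- c()
  stage <- function(name, expr) {
    pipeline_log(logcon, "stage ", name, " started")
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    dt <- proc.time()[["elapsed"]] - t0
    timings[[name]] <<- dt
    pipeline_log(logcon, "stage ", name, " done in ",
                 sprintf("%.2f s", dt))
    out
  }

  dat <- stage("data", {
    if (config$mode == "user-data") {
      cohort <- read_cohort(config$manifest)
      cm <- read_concentrations(config$concentrations, config$annotations,
                                config$censor_flags)
      list(cohort = cohort, matrix = cm)
    } else {
      cfg <- cohort_config(n_pairs = config$n_pairs, seed = config$seed)
      sim <- if (config$mode == "synthetic-null") null_cohort(cfg)
             else generate_cohort(cfg)
      write_cohort(sim$cohort, file.path(config$out_dir, "cohort.csv"))
      write_concentrations(sim$matrix,
                           file.path(config$out_dir, "concentrations.csv"),
                           file.path(config$out_dir, "annotations.csv"),
                           file.path(config$out_dir, "censor_flags.csv"))
      sim
    }
  })

  filt <- stage("qc_filter", {
    f <- filter_metabolites(flag_out_of_range(dat$matrix),
                            config$max_fraction)
    write_tsv_report(f$report, file.path(config$out_dir, "retention.tsv"))
    write_concentrations(f$matrix,
                         file.path(config$out_dir, "filtered.csv"),
                         file.path(config$out_dir,
                                   "filtered_annotations.csv"))
    f
  })

  uni <- stage("univariate", {
    um <- compare_groups(filt$matrix, dat$cohort$group,
                         pair = dat$cohort$pair_id, paired = config$paired,
                         alpha = config$alpha)
    write_tsv_report(um, file.path(config$out_dir,
                                   "univariate_metabolites.tsv"))
    ub <- NULL
    bm_cols <- intersect(default_biomarker_spec()$name, names(dat$cohort))
    if (length(bm_cols) >= 1L) {
      ub <- compare_groups(dat$cohort[, bm_cols, drop = FALSE],
                           dat$cohort$group, pair = dat$cohort$pair_id,
                           paired = config$paired, alpha = config$alpha)
      write_tsv_report(ub, file.path(config$out_dir,
                                     "univariate_biomarkers.tsv"))
    }
    list(metabolites = um, biomarkers = ub)
  })

  pca <- stage("pca_screen", {
    xm <- if (config$paired)
      within_pair_transform(filt$matrix, dat$cohort$pair_id)
    else filt$matrix$values
    sc <- autoscale(xm)
    fit <- pca_nipals(sc$train, n_components = 2)
    t2 <- hotelling_t2(fit)
    scores <- data.frame(sample_id = rownames(filt$matrix$values),
                         fit$scores, t2 = t2$t2, outlier = t2$outlier)
    write_tsv_report(scores, file.path(config$out_dir, "pca_scores.tsv"))
    list(fit = fit, t2 = t2)
  })

  val <- stage("validation", {
    plan <- partition_plan(n_pairs = length(unique(dat$cohort$pair_id)),
                           n_train_pairs = config$train_pairs,
                           step = config$step, offset = config$offset,
                           max_models = config$max_models)
    v <- run_validation(filt$matrix, dat$cohort$pair_id, dat$cohort$group,
                        plan, n_components = config$n_components,
                        paired = config$paired, alpha = config$alpha,
                        auroc_cutoff = config$auroc_cutoff,
                        p_cutoff = config$p_cutoff,
                        vip_cutoff = config$vip_cutoff,
                        stream = file.path(config$out_dir, "models.jsonl"))
    write_validation_histograms(v,
                                file.path(config$out_dir,
                                          "auroc_histogram.tsv"),
                                file.path(config$out_dir,
                                          "pvalue_histogram.tsv"))
    v
  })

  report <- list(
    mode = config$mode, seed = config$seed,
    n_samples = nrow(dat$matrix$values),
    n_pairs = length(unique(dat$cohort$pair_id)),
    retention = list(
      n_input = attr(filt$report, "n_input"),
      n_retained = attr(filt$report, "n_retained"),
      retained_fraction = attr(filt$report, "retained_fraction"),
      by_family = stats::aggregate(retained ~ family, data = filt$report,
                                   FUN = sum)),
    univariate = list(
      n_significant_metabolites = sum(uni$metabolites$significant),
      n_significant_biomarkers = if (is.null(uni$biomarkers)) NA_integer_
                                 else sum(uni$biomarkers$significant)),
    pca = list(explained_variance = pca$fit$explained_variance,
               n_outliers = sum(pca$t2$outlier),
               t2_limit = pca$t2$limit),
    validation = val[c("n_models", "mean_auroc", "median_auroc", "median_p",
                       "fraction_significant",
                       "fraction_significantly_better",
                       "fraction_significantly_worse", "decision",
                       "selected_variables")],
    timings = as.list(timings))
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- c(
    sprintf("Pipeline run (%s), seed %s", config$mode,
            if (is.null(config$seed)) "-" else config$seed),
    sprintf("Samples: %d (%d pairs)", report$n_samples, report$n_pairs),
    sprintf("Quantitation filter: %d of %d metabolites retained (%.1f%%)",
            report$retention$n_retained, report$retention$n_input,
            100 * report$retention$retained_fraction),
    sprintf("Univariate: %d metabolite(s) significant after BH",
            report$univariate$n_significant_metabolites),
    sprintf("PCA screen: %d Hotelling T2 outlier(s)", report$pca$n_outliers),
    sprintf("Validation: %d models, median AUROC %.3f, median p %.3f",
            report$validation$n_models, report$validation$median_auroc,
            report$validation$median_p),
    sprintf("  significantly different from mean model: %.1f%% (better %.1f%%, worse %.1f%%)",
            100 * report$validation$fraction_significant,
            100 * report$validation$fraction_significantly_better,
            100 * report$validation$fraction_significantly_worse),
    sprintf("  decision: %s; selected: %s",
            if (report$validation$decision) "satisfactory"
            else "not satisfactory",
            if (length(report$validation$selected_variables))
              paste(report$validation$selected_variables, collapse = ", ")
            else "<none>"))
  writeLines(txt, file.path(config$out_dir, "report.txt"))
  pipeline_log(logcon, "pipeline finished")
  invisible(report)
}
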