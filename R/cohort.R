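#' Default metabolite panel composition
#'
#' Family-level composition of the simulated targeted panel, modelled on a
#' Biocrates p180-style kit: 188 analytes across the acylcarnitine, amino
#' acid, biogenic amine, glycerophospholipid (lyso- and diacyl/acyl-alkyl
#' phosphatidylcholines), sphingomyelin and hexose families. `total` is the
#' number of analytes the kit measures in each family; `retained` is the
#' number designed to survive the 20% quantitation-accuracy filter
#' (12 + 21 + 12 + 12 + 70 + 14 + 1 = 142 of 188).
#'
#' @return A data.frame with columns `family`, `total`, `retained`.
#' @seealso [cohort_config()], [generate_cohort()]
#' @export
default_panel_spec <- function() {
  data.frame(
    family = c("acylcarnitines", "amino acids", "biogenic amines",
               "lysophosphatidylcholines", "phosphatidylcholines",
               "sphingomyelins", "hexoses"),
    total = c(40L, 21L, 21L, 14L, 76L, 15L, 1L),
    retained = c(12L, 21L, 12L, 12L, 70L, 14L, 1L),
    stringsAsFactors = FALSE
  )
}

#' Default group-effect specification for the effect mode
#'
#' Per-metabolite arithmetic mean and standard deviation (umol/L) in the
#' remodeling (LVR) and control (no-LVR) groups for the five analytes that
#' separate the groups in univariate analysis: symmetrical dimethylarginine
#' and sphingomyelin C20:2 higher under remodeling,
#' lysophosphatidylcholine C17:0 and phosphatidylcholines C40:6 and C42:3
#' lower.
#'
#' @return A data.frame with columns `name`, `lvr_mean`, `lvr_sd`,
#'   `ctrl_mean`, `ctrl_sd`.
#' @export
default_effect_spec <- function() {
  data.frame(
    name = c("SDMA", "SM C20:2", "lysoPC a C17:0", "PC aa C40:6",
             "PC aa C42:3"),
    lvr_mean  = c(0.57, 0.29, 1.13, 23.26, 0.47),
    lvr_sd    = c(0.15, 0.07, 0.30, 6.08, 0.10),
    ctrl_mean = c(0.52, 0.25, 1.37, 25.96, 0.52),
    ctrl_sd   = c(0.07, 0.05, 0.46, 6.48, 0.11),
    stringsAsFactors = FALSE
  )
}

#' Default routine-biomarker specification
#'
#' Group means and standard deviations for the routine clinical biomarkers
#' carried on the cohort manifest: creatine kinase peak (UI/L), C-reactive
#' protein (mg/L), leukocyte and neutrophil counts (/mL), NT-proBNP (ng/L)
#' and creatinine (umol/L). Remodeling patients carry higher necrosis and
#' inflammation markers.
#'
#' @return A data.frame with columns `name`, `lvr_mean`, `lvr_sd`,
#'   `ctrl_mean`, `ctrl_sd`.
#' @export
default_biomarker_spec <- function() {
  data.frame(
    name = c("ck_peak", "crp", "leukocytes", "neutrophils", "ntprobnp",
             "creatinine"),
    lvr_mean  = c(3466, 35.9, 12028, 9035, 1844, 74.8),
    lvr_sd    = c(2211, 44.3, 2593, 3036, 1882, 14.3),
    ctrl_mean = c(2394, 21.7, 10346, 7596, 1375, 72.2),
    ctrl_sd   = c(1615, 30.4, 3626, 3822, 1630, 15.3),
    stringsAsFactors = FALSE
  )
}

# Deterministic per-metabolite annotation table for a panel spec: names,
# family labels, design retention status, and baseline (control) mean/cv.
# Baseline means follow a fixed geometric grid per family so the panel is
# identical across seeds; effect metabolites get their configured means.
panel_metabolites <- function(panel_spec, effect_spec) {
  prefix <- c("acylcarnitines" = "AC",
              "amino acids" = "AA",
              "biogenic amines" = "BAm",
              "lysophosphatidylcholines" = "lysoPC a",
              "phosphatidylcholines" = "PC aa",
              "sphingomyelins" = "SM",
              "hexoses" = "H1")
  # typical concentration scale (umol/L) per family
  scale_lo <- c("acylcarnitines" = 0.02, "amino acids" = 15,
                "biogenic amines" = 0.1, "lysophosphatidylcholines" = 0.5,
                "phosphatidylcholines" = 0.5, "sphingomyelins" = 1,
                "hexoses" = 4000)
  scale_hi <- c("acylcarnitines" = 5, "amino acids" = 600,
                "biogenic amines" = 60, "lysophosphatidylcholines" = 100,
                "phosphatidylcholines" = 400, "sphingomyelins" = 200,
                "hexoses" = 6000)
  out <- lapply(seq_len(nrow(panel_spec)), function(i) {
    fam <- panel_spec$family[i]
    tot <- panel_spec$total[i]
    ret <- panel_spec$retained[i]
    nm <- paste(prefix[[fam]], sprintf("C%02d", seq_len(tot)))
    if (fam == "hexoses") nm <- "H1 (sum of hexoses)"
    means <- exp(seq(log(scale_lo[[fam]]), log(scale_hi[[fam]]),
                     length.out = tot))
    data.frame(name = nm, family = fam,
               designed_retained = seq_len(tot) <= ret,
               base_mean = means, base_cv = 0.25,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  # substitute the named effect metabolites for the first retained slots of
  # their families so their panel names match the field's nomenclature
  slot_family <- c("SDMA" = "biogenic amines",
                   "SM C20:2" = "sphingomyelins",
                   "lysoPC a C17:0" = "lysophosphatidylcholines",
                   "PC aa C40:6" = "phosphatidylcholines",
                   "PC aa C42:3" = "phosphatidylcholines")
  for (j in seq_len(nrow(effect_spec))) {
    nm <- effect_spec$name[j]
    fam <- if (nm %in% names(slot_family)) slot_family[[nm]] else
      out$family[match(nm, out$name)]
    if (nm %in% out$name) {
      k <- match(nm, out$name)
      out$base_mean[k] <- effect_spec$ctrl_mean[j]
      out$base_cv[k] <- effect_spec$ctrl_sd[j] / effect_spec$ctrl_mean[j]
      next
    }
    slot <- which(out$family == fam & out$designed_retained &
                    !(out$name %in% effect_spec$name))
    if (length(slot) == 0L)
      stop("no retained slot left in family '", fam,
           "' for effect metabolite '", nm, "'")
    k <- slot[length(slot)]
    out$name[k] <- nm
    out$base_mean[k] <- effect_spec$ctrl_mean[j]
    out$base_cv[k] <- effect_spec$ctrl_sd[j] / effect_spec$ctrl_mean[j]
  }
  rownames(out) <- NULL
  out
}

#' Configuration for the synthetic matched-cohort generator
#'
#' Assembles and validates all parameters of the simulator: cohort size,
#' panel composition, group effects, routine biomarkers, within-pair
#' correlation, censoring probabilities and seed.
#'
#' @param n_pairs Number of matched case-control pairs (default 32, i.e.
#'   64 subjects).
#' @param panel_spec Panel composition, as [default_panel_spec()]: one row
#'   per family with `total` analytes of which `retained` are designed to
#'   pass the quantitation filter.
#' @param effect_spec Group means/sds (umol/L) for effect metabolites, as
#'   [default_effect_spec()]. Ignored when the cohort is generated in null
#'   mode.
#' @param biomarker_spec Group means/sds for routine biomarkers, as
#'   [default_biomarker_spec()].
#' @param pair_correlation Within-pair correlation of the standardized
#'   log-concentrations induced by matching, in `[0, 1)`. Default 0.3.
#' @param censor_retained Probability that a single measurement of a
#'   designed-retained metabolite falls outside its quantitation limits.
#'   Default 0.02.
#' @param censor_failing Same probability for metabolites designed to fail
#'   the 20% filter. Default 0.6.
#' @param hypertension_prev Length-2 numeric, prevalence of hypertension in
#'   the remodeling and control groups.
#' @param seed Integer seed; required for reproducible generation.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @examples
#' cfg <- cohort_config(seed = 1)
#' cfg$n_pairs
#' @export
cohort_config <- function(n_pairs = 32L,
                          panel_spec = default_panel_spec(),
                          effect_spec = default_effect_spec(),
                          biomarker_spec = default_biomarker_spec(),
                          pair_correlation = 0.3,
                          censor_retained = 0.02,
                          censor_failing = 0.6,
                          hypertension_prev = c(lvr = 0.563, ctrl = 0.25),
                          seed = NULL) {
  n_pairs <- as.integer(n_pairs)
  if (is.na(n_pairs) || n_pairs < 2L)
    stop("'n_pairs' must be an integer >= 2")
  req <- c("family", "total", "retained")
  if (!all(req %in% names(panel_spec)))
    stop("'panel_spec' needs columns family, total, retained")
  if (any(panel_spec$retained > panel_spec$total) ||
      any(panel_spec$total < 1L))
    stop("malformed 'panel_spec': need 1 <= retained <= total per family")
  eff <- c("name", "lvr_mean", "lvr_sd", "ctrl_mean", "ctrl_sd")
  if (!all(eff %in% names(effect_spec)))
    stop("'effect_spec' needs columns ", paste(eff, collapse = ", "))
  if (any(effect_spec$lvr_sd <= 0) || any(effect_spec$ctrl_sd <= 0) ||
      any(biomarker_spec$lvr_sd <= 0) || any(biomarker_spec$ctrl_sd <= 0))
    stop("all standard deviations must be > 0")
  if (any(effect_spec$lvr_mean <= 0) || any(effect_spec$ctrl_mean <= 0))
    stop("all effect means must be > 0")
  if (!is.numeric(pair_correlation) || pair_correlation < 0 ||
      pair_correlation >= 1)
    stop("'pair_correlation' must lie in [0, 1)")
  if (censor_retained < 0 || censor_retained >= 1 ||
      censor_failing <= 0 || censor_failing >= 1)
    stop("censoring probabilities must lie in [0, 1)")
  if (!is.null(seed)) seed <- as.integer(seed)
  structure(list(n_pairs = n_pairs, panel_spec = panel_spec,
                 effect_spec = effect_spec, biomarker_spec = biomarker_spec,
                 pair_correlation = pair_correlation,
                 censor_retained = censor_retained,
                 censor_failing = censor_failing,
                 hypertension_prev = hypertension_prev,
                 seed = seed),
            class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic matched-cohort configuration\n")
  cat("  pairs:", x$n_pairs, " (", 2L * x$n_pairs, "subjects )\n")
  cat("  panel:", sum(x$panel_spec$total), "metabolites,",
      sum(x$panel_spec$retained), "designed to pass the quantitation filter\n")
  cat("  effect metabolites:", paste(x$effect_spec$name, collapse = ", "),
      "\n")
  cat("  within-pair correlation:", x$pair_correlation,
      "  seed:", if (is.null(x$seed)) "<none>" else x$seed, "\n")
  invisible(x)
}

# moment-matched log-normal parameters for arithmetic mean m and sd s
lnorm_params <- function(m, s) {
  sigma2 <- log1p((s / m)^2)
  list(mu = log(m) - sigma2 / 2, sigma = sqrt(sigma2))
}

#' Generate a synthetic matched case-control cohort
#'
#' Draws a matched cohort (one remodeling and one control subject per pair)
#' and a samples-by-metabolites concentration matrix with the statistical
#' structure the downstream analysis assumes. Concentrations are log-normal,
#' moment-matched to the configured arithmetic group means and standard
#' deviations; matching induces a within-pair correlation
#' (`pair_correlation`) through a shared pair-level random intercept on the
#' standardized log scale, so the marginal distribution of each metabolite
#' is exactly the configured log-normal. Each metabolite receives a lower
#' limit of quantitation placed at the quantile of its control-group
#' distribution that yields the configured out-of-range probability, so the
#' designed-to-fail analytes exceed the 20% censoring threshold with
#' near-certainty while retained analytes stay far below it.
#'
#' @param config A [cohort_config()].
#' @param effects Logical; if `FALSE` every metabolite and biomarker uses
#'   its control-group distribution in both groups (null mode).
#' @param antithetic Logical; if `TRUE` every standardized normal deviate of
#'   the concentration and biomarker models is sign-flipped while consuming
#'   the identical random stream. Generating each seed once normally and
#'   once antithetically yields a negatively correlated pair of cohorts
#'   with the same marginal distribution -- the classic variance-reduction
#'   device for simulation studies of mean recovery.
#' @return A list with components
#'   \describe{
#'     \item{cohort}{data.frame manifest: `subject_id`, `pair_id`, `group`
#'       (`"LVR"`/`"noLVR"`), clinical covariates and routine biomarkers.}
#'     \item{matrix}{a [conc_matrix] of concentrations (umol/L) with
#'       per-metabolite family annotation, quantitation limits and censor
#'       flags.}
#'   }
#' @examples
#' sim <- generate_cohort(cohort_config(seed = 7))
#' table(sim$cohort$group)
#' dim(sim$matrix$values)
#' @seealso [null_cohort()], [flag_out_of_range()], [filter_metabolites()]
#' @export
generate_cohort <- function(config, effects = TRUE, antithetic = FALSE) {
  if (!inherits(config, "cohort_config"))
    config <- do.call(cohort_config, config)
  if (!is.null(config$seed)) set.seed(config$seed)
  flip <- if (antithetic) -1 else 1
  np <- config$n_pairs
  rho <- config$pair_correlation
  ann <- panel_metabolites(config$panel_spec, config$effect_spec)
  p <- nrow(ann)

  # per-metabolite, per-group log-normal parameters
  ctrl <- lnorm_params(ann$base_mean, ann$base_cv * ann$base_mean)
  mu0 <- ctrl$mu; sg0 <- ctrl$sigma
  mu1 <- mu0; sg1 <- sg0
  if (effects) {
    idx <- match(config$effect_spec$name, ann$name)
    if (anyNA(idx)) stop("effect metabolite missing from panel: ",
                         paste(config$effect_spec$name[is.na(idx)],
                               collapse = ", "))
    lv <- lnorm_params(config$effect_spec$lvr_mean, config$effect_spec$lvr_sd)
    mu1[idx] <- lv$mu; sg1[idx] <- lv$sigma
  }

  # shared pair intercept + subject noise on the standardized log scale
  u <- flip * matrix(stats::rnorm(np * p), np, p)
  e_lvr <- flip * matrix(stats::rnorm(np * p), np, p)
  e_ctl <- flip * matrix(stats::rnorm(np * p), np, p)
  z_lvr <- sqrt(rho) * u + sqrt(1 - rho) * e_lvr
  z_ctl <- sqrt(rho) * u + sqrt(1 - rho) * e_ctl
  x_lvr <- exp(sweep(sweep(z_lvr, 2, sg1, `*`), 2, mu1, `+`))
  x_ctl <- exp(sweep(sweep(z_ctl, 2, sg0, `*`), 2, mu0, `+`))

  values <- matrix(0, 2L * np, p)
  values[seq(1L, 2L * np, by = 2L), ] <- x_lvr
  values[seq(2L, 2L * np, by = 2L), ] <- x_ctl

  # quantitation limits: censoring acts from below (low-abundance analytes);
  # the upper limit sits far in the right tail of the control distribution
  pc <- ifelse(ann$designed_retained, config$censor_retained,
               config$censor_failing)
  lloq <- stats::qlnorm(pc, mu0, sg0)
  uloq <- stats::qlnorm(1 - 1e-9, pmax(mu0, mu1), pmax(sg0, sg1)) * 2

  pair_id <- sprintf("pair%02d", rep(seq_len(np), each = 2L))
  group <- rep(c("LVR", "noLVR"), np)
  subject_id <- sprintf("S%03d_%s", rep(seq_len(np), each = 2L), group)
  rownames(values) <- subject_id
  colnames(values) <- ann$name

  annotations <- data.frame(name = ann$name, family = ann$family,
                            lloq = lloq, uloq = uloq,
                            stringsAsFactors = FALSE)
  cm <- conc_matrix(values, annotations)

  # clinical covariates: matching keeps age and sex common within a pair
  age_base <- stats::rnorm(np, 58, 9)
  age <- round(rep(age_base, each = 2L) + stats::rnorm(2L * np, 0, 1.5))
  sex <- rep(ifelse(stats::runif(np) < 0.81, "M", "F"), each = 2L)
  prev <- if (effects) config$hypertension_prev
          else rep(config$hypertension_prev[["ctrl"]], 2L)
  hyper <- ifelse(group == "LVR",
                  stats::runif(2L * np) < prev[[1]],
                  stats::runif(2L * np) < prev[[2]])

  cohort <- data.frame(subject_id = subject_id, pair_id = pair_id,
                       group = group, age = age, sex = sex,
                       hypertension = hyper, stringsAsFactors = FALSE)

  bm <- config$biomarker_spec
  ub <- flip * matrix(stats::rnorm(np * nrow(bm)), np)
  for (j in seq_len(nrow(bm))) {
    p0 <- lnorm_params(bm$ctrl_mean[j], bm$ctrl_sd[j])
    p1 <- if (effects) lnorm_params(bm$lvr_mean[j], bm$lvr_sd[j]) else p0
    z1 <- sqrt(rho) * ub[, j] + sqrt(1 - rho) * flip * stats::rnorm(np)
    z0 <- sqrt(rho) * ub[, j] + sqrt(1 - rho) * flip * stats::rnorm(np)
    v <- numeric(2L * np)
    v[seq(1L, 2L * np, by = 2L)] <- exp(p1$mu + p1$sigma * z1)
    v[seq(2L, 2L * np, by = 2L)] <- exp(p0$mu + p0$sigma * z0)
    cohort[[bm$name[j]]] <- v
  }

  list(cohort = cohort, matrix = cm)
}

#' Generate a null-mode cohort (no group effects)
#'
#' Identical in structure to [generate_cohort()] but every metabolite and
#' biomarker follows its control-group distribution in both groups, making
#' the group labels exchangeable. Used as the reference condition when
#' calibrating the validation engine against the mean (no-information)
#' model.
#'
#' @inheritParams generate_cohort
#' @return As [generate_cohort()].
#' @export
null_cohort <- function(config) {
  generate_cohort(config, effects = FALSE)
}
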