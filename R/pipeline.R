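# Orchestration: seeded end-to-end runs over a simulated (or ingested)
# study, writing every stage's output as CSV plus a JSON manifest, and
# report tables formatted at the printed precision (odds ratios at one
# decimal, proportions as whole percentages) with full precision retained
# in companion columns.

#' Build a pipeline run configuration
#'
#' @param out_dir output directory for stage results.
#' @param seed master seed; every stochastic stage derives its own stream.
#' @param sim a [sim_config()] describing the study to simulate; its seed is
#'   overridden by `seed`.
#' @param alpha elastic-net mixing parameter.
#' @param B bootstrap resamples for stability selection.
#' @param B_plspm bootstrap resamples for path-model intervals.
#' @param stabsel_retune re-tune lambda inside each stability resample.
#' @param n_components PLS-DA components.
#' @param cv_folds,cv_repeats PLS-DA cross-validation scheme.
#' @param stages character vector of stage names to run (default all).
#' @param cutoffs a [clinical_cutoffs()] object.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1, sim = sim_config(seed = seed),
                       alpha = 0.5, B = 1000, B_plspm = 1000,
                       stabsel_retune = TRUE,
                       n_components = 2, cv_folds = 5, cv_repeats = 50,
                       stages = c("simulate", "match", "qc", "univariate",
                                  "stabsel", "plsda", "correlate", "plspm",
                                  "report"),
                       cutoffs = clinical_cutoffs()) {
  sim$seed <- seed
  structure(list(out_dir = out_dir, seed = seed, sim = sim, alpha = alpha,
                 B = B, B_plspm = B_plspm, stabsel_retune = stabsel_retune,
                 n_components = n_components, cv_folds = cv_folds,
                 cv_repeats = cv_repeats, stages = stages, cutoffs = cutoffs),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML file may set any scalar argument of [run_config()] (seed, alpha,
#' B, cv scheme, stages, cutoff overrides) plus a `sim:` mapping of
#' [sim_config()] arguments.
#'
#' @param path YAML file.
#' @param out_dir output directory (overrides any value in the file).
#' @return a [run_config()].
#' @export
run_config_from_yaml <- function(path, out_dir) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  y$sim <- NULL
  cut_args <- y$cutoffs %||% list()
  y$cutoffs <- NULL
  y$out_dir <- out_dir
  y$sim <- do.call(sim_config, sim_args)
  y$cutoffs <- do.call(clinical_cutoffs, cut_args)
  do.call(run_config, y)
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Stages, in order: simulate the study; propensity-match survivors to
#' nonsurvivors 1:1; quality-filter and impute the metabolome; matched
#' univariate conditional-logistic screen with BH-FDR; bootstrap elastic-net
#' stability selection; union into the differential feature set; multilevel
#' PLS-DA with pair-grouped cross-validation; FDR-screened marker/systemic
#' correlations; PLS path model with bootstrap intervals; report tables.
#' Rerunning with the same configuration reproduces every output.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list of in-memory stage results; files are written
#'   under `config$out_dir` and enumerated in `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$out_dir, ...)
  res <- list(config = config)
  st <- config$stages

  study <- simulate_study(config$sim)
  res$study <- study
  if ("simulate" %in% st) {
    write_cohort(study$cohort, out("subjects.csv"))
    write_analyte_matrix(study$metabolome, out("metabolites.csv"), out("analytes.csv"))
    utils::write.csv(study$water, out("water.csv"), row.names = FALSE, quote = FALSE)
    write_analyte_matrix(study$markers, out("markers.csv"), out("marker_meta.csv"))
    write_analyte_matrix(study$systemic, out("systemic.csv"), out("systemic_meta.csv"))
    jsonlite::write_json(study$truth[c("differential", "unstable", "low_detection",
                                       "latent_paths", "mortality_coef")],
                         out("ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }

  pm <- fit_propensity(study$cohort)
  matched <- match_pairs(pm, study$cohort)
  res$matched <- matched
  if ("match" %in% st) {
    utils::write.csv(matched$pairs, out("pairs.csv"), row.names = FALSE, quote = FALSE)
  }
  pairs <- matched$pairs
  matched_ids <- c(pairs$case_id, pairs$control_id)
  group <- setNames(matched$subjects$group, matched$subjects$subject_id)

  # qc: filter on matched study samples + QC rows, then impute
  met <- study$metabolome
  keep_rows <- rownames(met$values)[met$is_qc | rownames(met$values) %in% matched_ids]
  met <- analyte_matrix(met$values[keep_rows, , drop = FALSE], met$units,
                        met$analyte_class, basis = met$basis,
                        is_qc = met$is_qc[keep_rows])
  freport <- filter_report(met, group)
  filtered <- impute_missing(apply_filter(met, freport))
  res$filter_report <- freport
  res$filtered <- filtered
  if ("qc" %in% st) {
    utils::write.csv(freport, out("filter_report.csv"), row.names = FALSE, quote = FALSE)
    write_analyte_matrix(filtered, out("filtered.csv"), out("filtered_analytes.csv"))
  }

  X_log <- transform_standardize(filtered)                 # log10
  uni <- univariate_screen(X_log, pairs)
  res$univariate <- uni
  if ("univariate" %in% st) {
    utils::write.csv(uni, out("univariate.csv"), row.names = FALSE, quote = FALSE)
  }
  uni_hits <- uni$analyte_id[!is.na(uni$p) & uni$p < 0.05]

  if ("stabsel" %in% st) {
    Xz <- transform_standardize(filtered, standardize = TRUE)
    y <- as.integer(group[rownames(Xz)] == "case")
    stab <- bootstrap_stability(Xz, y, pairs = pairs, alpha = config$alpha,
                                B = config$B, seed = derive_seed(config$seed, "stabsel"),
                                retune = config$stabsel_retune)
    res$stability <- stab
    utils::write.csv(stab, out("stability.csv"), row.names = FALSE, quote = FALSE)
    influential <- stab$analyte_id[stab$influential]
  } else {
    influential <- character()
  }
  diffset <- differential_feature_union(uni_hits, influential)
  res$differential <- diffset
  utils::write.csv(diffset, out("differential.csv"), row.names = FALSE, quote = FALSE)

  if ("plsda" %in% st && nrow(diffset) >= 2) {
    Xd <- X_log[, diffset$analyte_id, drop = FALSE]
    cvp <- cross_validate_plsda(Xd, group[rownames(Xd)], pairs,
                                n_components = config$n_components,
                                folds = config$cv_folds,
                                repeats = config$cv_repeats,
                                seed = derive_seed(config$seed, "plsda"))
    res$plsda_cv <- cvp
    perf <- data.frame(metric = c("auc", "misclassification"),
                       mean = c(cvp$auc_mean, cvp$mcr_mean),
                       sd = c(cvp$auc_sd, cvp$mcr_sd))
    utils::write.csv(perf, out("plsda_performance.csv"), row.names = FALSE, quote = FALSE)
  }

  # marker exceedance on wet basis
  exc <- flag_exceedance(study$markers, config$cutoffs, group)
  res$exceedance <- exc
  utils::write.csv(exc$proportions, out("exceedance.csv"), row.names = FALSE, quote = FALSE)

  if ("correlate" %in% st) {
    mk <- log10(study$markers$values[matched_ids, c("calprotectin", "mpo", "aat"),
                                     drop = FALSE])
    sy <- log10(study$systemic$values[matched_ids, , drop = FALSE])
    corr <- pairwise_pearson_fdr(cbind(mk, sy))
    res$correlations <- corr
    utils::write.csv(data.frame(analyte = rownames(corr$r), corr$r, check.names = FALSE),
                     out("correlations.csv"), row.names = FALSE, quote = FALSE)
  }

  if ("plspm" %in% st && sum(diffset$analyte_id %in% colnames(X_log)) >= 2) {
    mets <- diffset$analyte_id
    dat <- cbind(log10(study$markers$values[matched_ids, c("calprotectin", "mpo")]),
                 X_log[matched_ids, mets, drop = FALSE],
                 log10(study$systemic$values[matched_ids, , drop = FALSE]),
                 mortality = as.numeric(group[matched_ids] == "case"))
    dat <- dat[stats::complete.cases(dat), , drop = FALSE]
    spec <- default_path_spec(mets)
    bp <- bootstrap_paths(dat, spec, B = config$B_plspm,
                          seed = derive_seed(config$seed, "plspm"))
    res$plspm <- bp
    utils::write.csv(bp$paths, out("plspm_paths.csv"), row.names = FALSE, quote = FALSE)
    utils::write.csv(bp$effects, out("plspm_effects.csv"), row.names = FALSE, quote = FALSE)
    utils::write.csv(data.frame(index = c("gof", paste0("r2_", names(bp$fit$r2))),
                                value = c(bp$fit$gof, unname(bp$fit$r2))),
                     out("plspm_fit_indices.csv"), row.names = FALSE, quote = FALSE)
  }

  manifest <- list(seed = config$seed,
                   stages = st,
                   n_subjects = nrow(study$cohort$subjects),
                   n_pairs = nrow(pairs),
                   n_retained = sum(freport$retained),
                   n_differential = nrow(diffset),
                   files = list.files(config$out_dir))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE, digits = NA)
  if ("report" %in% st) make_report(config$out_dir)
  invisible(res)
}

#' Admission characteristics table with 2x2 odds ratios
#'
#' For each binary covariate, counts and percentages per group and the
#' unadjusted case/control odds ratio with Woolf 95% interval, formatted at
#' one decimal (half-up) with full precision kept in companion columns.
#'
#' @param cohort a [cohort()].
#' @param covariates names of logical subject columns to tabulate.
#' @return data.frame, one row per covariate.
#' @export
characteristics_table <- function(cohort,
                                  covariates = c("edema", "diarrhea", "breastfed")) {
  s <- cohort$subjects
  s <- s[s$group %in% c("case", "control"), , drop = FALSE]
  rows <- lapply(covariates, function(cv) {
    x <- s[[cv]]
    ok <- !is.na(x)
    a <- sum(x[ok] & s$group[ok] == "case")
    b <- sum(!x[ok] & s$group[ok] == "case")
    cc <- sum(x[ok] & s$group[ok] == "control")
    d <- sum(!x[ok] & s$group[ok] == "control")
    or_ <- odds_ratio_2x2(a, b, cc, d)
    data.frame(covariate = cv,
               case_n = a, case_total = a + b,
               case_pct = round_half_up(100 * a / (a + b)),
               control_n = cc, control_total = cc + d,
               control_pct = round_half_up(100 * cc / (cc + d)),
               or_ = or_$or_, ci_low = or_$ci_low, ci_high = or_$ci_high,
               formatted = sprintf("%.1f [%.1f, %.1f]",
                                   round_half_up(or_$or_, 1),
                                   round_half_up(or_$ci_low, 1),
                                   round_half_up(or_$ci_high, 1)))
  })
  do.call(rbind, rows)
}

#' Assemble report tables from a pipeline run directory
#'
#' Pure function of the stage CSVs: characteristics table with odds ratios,
#' differential-feature table, marker exceedance proportions (whole
#' percentages), and path-effects table. Missing stage outputs are listed
#' rather than silently skipped.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return (invisibly) list of report data.frames; written as report_*.csv.
#' @export
make_report <- function(run_dir) {
  need <- c("subjects.csv", "differential.csv", "exceedance.csv")
  absent <- need[!file.exists(file.path(run_dir, need))]
  if (length(absent) > 0) {
    stop_mm("mm_pipeline_error", "missing stage output(s): %s",
            paste(absent, collapse = ", "))
  }
  coh <- read_cohort(file.path(run_dir, "subjects.csv"))
  rep_ <- list()
  rep_$characteristics <- characteristics_table(coh)

  diffs <- utils::read.csv(file.path(run_dir, "differential.csv"),
                           stringsAsFactors = FALSE)
  if (nrow(diffs) == 0) {
    message("no differential features; downstream report sections skipped")
  }
  rep_$differential <- diffs

  exc <- utils::read.csv(file.path(run_dir, "exceedance.csv"),
                         stringsAsFactors = FALSE)
  exc$pct <- round_half_up(100 * exc$proportion)
  rep_$exceedance <- exc

  pe <- file.path(run_dir, "plspm_effects.csv")
  if (file.exists(pe)) rep_$path_effects <- utils::read.csv(pe, stringsAsFactors = FALSE)

  for (nm in names(rep_)) {
    utils::write.csv(rep_[[nm]], file.path(run_dir, paste0("report_", nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(rep_)
}
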