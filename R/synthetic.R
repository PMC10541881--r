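# Seeded synthetic-study generator with known ground truth.
#
# Emulates the structure of a nested matched case-control study of
# complicated severe malnutrition: a survivor pool and nonsurvivor cases, a
# targeted fecal metabolome (~68 metabolites in 6 classes, log-normal
# concentrations, below-detection missingness, QC replicates), fecal water
# content in the 60-85% range, enteropathy markers, systemic analytes, and a
# four-latent causal chain (intestinal inflammation -> luminal metabolism
# (-); intestinal inflammation -> circulating microbial products (+) ->
# systemic inflammation (+) -> mortality (+)).  Every logical block draws
# from its own sub-seeded random stream, so adding one block never perturbs
# another.

MET_CLASSES <- c("SCFA", "carboxylic acid", "carbohydrate",
                 "amino acid and derivative", "alcohol", "other")

#' Configuration for the synthetic study generator
#'
#' Defaults encode the emulated study conditions: 68 expected cases against
#' a survivor pool of 653; 68 targeted metabolites whose class shares are
#' SCFA 0.30, carboxylic acids 0.26, carbohydrates 0.19, amino acids and
#' derivatives 0.13, alcohols 0.09, other 0.03; a 15-metabolite differential
#' set (amino acids and carbohydrates first) shifted by -0.3 log10 in cases
#' — the factor-two reduction matching the observed total amino acid anchor
#' (95.8 vs 191.8 umol/g dry weight); 3 QC-unstable plus 4 low-detection
#' analytes so the quality filters remove 7 of 68; water content uniform on
#' (0.60, 0.85); and standardized latent paths (-0.4, +0.5, +0.5) with a
#' positive systemic-inflammation effect on the mortality logit.
#'
#' @param seed master integer seed; fully determines the simulated study.
#' @param n_cases expected number of cases (nonsurvivors).
#' @param n_control_pool size of the survivor pool.
#' @param n_metabolites number of targeted fecal metabolites.
#' @param class_proportions named per-class fractions summing to 1.
#' @param n_differential size of the true differential metabolite set.
#' @param effect_log10 case-minus-control shift (log10) for differential
#'   metabolites.
#' @param n_unstable number of QC-unstable analytes (CV above the filter).
#' @param n_low_detection number of analytes censored below the detection
#'   filter in both groups.
#' @param lod_quantile detection-limit quantile for ordinary analytes.
#' @param lod_quantile_low detection-limit quantile for low-detection
#'   analytes.
#' @param qc_cv target QC coefficient of variation for stable analytes.
#' @param qc_cv_unstable target QC CV for unstable analytes.
#' @param n_qc number of QC replicate rows.
#' @param water_range range of fecal water fractions.
#' @param latent_paths named standardized path coefficients `ii_lm`
#'   (inflammation -> luminal metabolism), `ii_cmp` (-> circulating
#'   microbial products), `cmp_si` (-> systemic inflammation).
#' @param mortality_coef named mortality log-odds: per-unit effects of the
#'   systemic inflammation latent (`si`), edema, MUAC (per cm, centered),
#'   HIV strata.
#' @param met_latent_loading log10-scale loading of the luminal metabolism
#'   latent on differential metabolites.
#' @param met_sd residual sd of log10 metabolite concentrations.
#' @param ifabp_edema_effect case shift of log10 serum I-FABP among
#'   non-edematous children only (edema-modified effect scenario; 0 = off).
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1,
                       n_cases = 68,
                       n_control_pool = 653,
                       n_metabolites = 68,
                       class_proportions = c("SCFA" = 0.30,
                                             "carboxylic acid" = 0.26,
                                             "carbohydrate" = 0.19,
                                             "amino acid and derivative" = 0.13,
                                             "alcohol" = 0.09,
                                             "other" = 0.03),
                       n_differential = 15,
                       effect_log10 = -0.3,
                       n_unstable = 3,
                       n_low_detection = 4,
                       lod_quantile = 0.05,
                       lod_quantile_low = 0.50,
                       qc_cv = 0.10,
                       qc_cv_unstable = 0.50,
                       n_qc = 8,
                       water_range = c(0.60, 0.85),
                       latent_paths = c(ii_lm = -0.4, ii_cmp = 0.5, cmp_si = 0.5),
                       mortality_coef = c(si = 0.6, edema = 0.3, muac = -0.25,
                                          hiv_positive = 1.1, hiv_unknown = 1.6),
                       met_latent_loading = 0.25,
                       met_sd = 0.5,
                       ifabp_edema_effect = 0) {
  if (abs(sum(class_proportions) - 1) > 1e-9) {
    stop_mm("mm_config_error", "class_proportions must sum to 1")
  }
  if (!all(names(class_proportions) %in% MET_CLASSES)) {
    stop_mm("mm_config_error", "unknown metabolite class in class_proportions")
  }
  if (n_cases > n_cases + n_control_pool) {
    stop_mm("mm_config_error", "n_cases exceeds the cohort pool")
  }
  if (n_differential + n_unstable + n_low_detection > n_metabolites) {
    stop_mm("mm_config_error", "designated analyte sets exceed n_metabolites")
  }
  if (qc_cv < 0 || qc_cv_unstable < 0) stop_mm("mm_config_error", "qc_cv must be >= 0")
  if (n_qc < 2) stop_mm("mm_config_error", "need at least 2 QC replicates")
  if (water_range[1] <= 0 || water_range[2] >= 1 || water_range[1] > water_range[2]) {
    stop_mm("mm_config_error", "water_range must lie inside (0,1)")
  }
  if (lod_quantile < 0 || lod_quantile >= 1) {
    stop_mm("mm_config_error", "lod_quantile must lie in [0,1)")
  }
  structure(as.list(environment()), class = "sim_config")
}

# Deterministic metabolite panel: ids, classes (largest-remainder
# apportionment of the class shares), the differential set (amino acids and
# carbohydrates first, mirroring where the group effects concentrate), and
# the designated QC-unstable / low-detection analytes (non-differential).
metabolite_panel <- function(config) {
  p <- config$n_metabolites
  counts <- floor(config$class_proportions * p)
  rem <- config$class_proportions * p - counts
  short <- p - sum(counts)
  if (short > 0) {
    add <- names(sort(rem, decreasing = TRUE))[seq_len(short)]
    counts[add] <- counts[add] + 1
  }
  classes <- rep(names(counts), counts)
  ids <- sprintf("met%02d", seq_len(p))
  pri <- order(match(classes, c("amino acid and derivative", "carbohydrate",
                                "carboxylic acid", "SCFA", "alcohol", "other")))
  differential <- ids[pri[seq_len(config$n_differential)]]
  rest <- setdiff(ids[pri], differential)
  unstable <- rev(rest)[seq_len(config$n_unstable)]
  low_det <- setdiff(rev(rest), unstable)[seq_len(config$n_low_detection)]
  base_by_class <- c("SCFA" = 1.6, "carboxylic acid" = 1.0, "carbohydrate" = 1.2,
                     "amino acid and derivative" = 1.33, "alcohol" = 0.8,
                     "other" = 0.5)
  list(ids = ids, classes = setNames(classes, ids),
       baseline_log10 = setNames(base_by_class[classes], ids),
       differential = differential, unstable = unstable, low_detection = low_det)
}

#' Simulate a full synthetic study with known ground truth
#'
#' Generates subject covariates, per-subject latent scores along the causal
#' chain, a Bernoulli mortality outcome from a logistic model (intercept
#' calibrated so the expected case count matches `n_cases`), a fecal
#' metabolite matrix on the dry-weight basis (class baseline + case effect +
#' latent contribution + log10-normal noise, left-censored at the detection
#' limit, with QC replicate rows appended), fecal water content, enteropathy
#' markers (wet basis + serum I-FABP) and systemic analytes. Identical seeds
#' give identical output.
#'
#' @param config a [sim_config()].
#' @return list with elements `cohort` (no pairs; group = case/control),
#'   `metabolome` (an [analyte_matrix()], dry basis, QC rows flagged),
#'   `water` (data.frame sample_id, water_fraction), `markers`
#'   (analyte_matrix, wet basis), `systemic` (analyte_matrix, serum basis)
#'   and `truth` (ground-truth list: differential set, designated failing
#'   analytes, latent paths and scores, mortality probabilities).
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_cases + config$n_control_pool
  ids <- sprintf("s%04d", seq_len(n))

  # --- covariates ---
  set.seed(derive_seed(config$seed, "covariates"))
  age <- pmax(2, round(exp(stats::rnorm(n, log(15), 0.6)), 1))
  muac <- pmax(6, round(stats::rnorm(n, 10.7, 1.5), 1))
  hiv <- sample(HIV_LEVELS, n, replace = TRUE, prob = c(0.73, 0.22, 0.05))
  edema <- stats::runif(n) < 0.31
  site <- sample(c("QECH", "Kilifi", "CPGH"), n, replace = TRUE,
                 prob = c(0.40, 0.23, 0.37))
  diarrhea <- stats::runif(n) < 0.42
  breastfed <- stats::runif(n) < 0.44
  sex <- sample(c("female", "male"), n, replace = TRUE, prob = c(0.46, 0.54))
  arm <- sample(c("intervention", "control_arm"), n, replace = TRUE)

  # --- latent chain (standardized scores) ---
  set.seed(derive_seed(config$seed, "latent"))
  pth <- config$latent_paths
  ii <- stats::rnorm(n)
  lm_ <- pth["ii_lm"] * ii + sqrt(1 - pth["ii_lm"]^2) * stats::rnorm(n)
  cmp <- pth["ii_cmp"] * ii + sqrt(1 - pth["ii_cmp"]^2) * stats::rnorm(n)
  si <- pth["cmp_si"] * cmp + sqrt(1 - pth["cmp_si"]^2) * stats::rnorm(n)
  latent <- cbind(II = ii, LM = lm_, CMP = cmp, SI = si)
  rownames(latent) <- ids

  # --- mortality ---
  set.seed(derive_seed(config$seed, "outcome"))
  mc <- config$mortality_coef
  eta <- mc["si"] * si + mc["edema"] * edema + mc["muac"] * (muac - mean(muac)) +
    mc["hiv_positive"] * (hiv == "positive") + mc["hiv_unknown"] * (hiv == "unknown")
  target <- config$n_cases / n
  # calibrate the intercept so mean death probability hits the target rate
  icpt <- stats::optimize(function(b) (mean(stats::plogis(b + eta)) - target)^2,
                          c(-15, 5))$minimum
  prob <- stats::plogis(icpt + eta)
  died <- stats::rbinom(n, 1, prob) == 1
  if (!any(died) || all(died)) {
    stop_mm("mm_config_error", "degenerate outcome draw: all or no subjects died")
  }

  subjects <- data.frame(
    subject_id = ids, group = ifelse(died, "case", "control"),
    age_months = age, muac_cm = muac, hiv = hiv, edema = edema, site = site,
    diarrhea = diarrhea, breastfed = breastfed, sex = sex,
    intervention_arm = arm, stringsAsFactors = FALSE)

  # --- fecal metabolome (dry basis, log10 umol/g) ---
  panel <- metabolite_panel(config)
  p <- config$n_metabolites
  set.seed(derive_seed(config$seed, "metabolome"))
  eff <- setNames(rep(0, p), panel$ids)
  eff[panel$differential] <- config$effect_log10
  lam <- setNames(rep(0, p), panel$ids)
  lam[panel$differential] <- config$met_latent_loading
  log10c <- matrix(stats::rnorm(n * p, 0, config$met_sd), n, p,
                   dimnames = list(ids, panel$ids))
  log10c <- log10c +
    matrix(panel$baseline_log10, n, p, byrow = TRUE) +
    outer(as.numeric(died), eff) +
    outer(lm_, lam)
  conc <- 10^log10c
  # left-censor below the per-analyte detection-limit quantile
  lodq <- setNames(rep(config$lod_quantile, p), panel$ids)
  lodq[panel$low_detection] <- config$lod_quantile_low
  for (j in seq_len(p)) {
    if (lodq[j] <= 0) next
    lod <- stats::quantile(conc[, j], lodq[j], names = FALSE)
    conc[conc[, j] < lod, j] <- NA
  }
  metabolome <- analyte_matrix(
    conc, units = setNames(rep("umol/g dry", p), panel$ids),
    analyte_class = panel$classes, basis = "dry")
  metabolome <- simulate_qc_replicates(metabolome, config)

  # --- water content ---
  set.seed(derive_seed(config$seed, "water"))
  water <- data.frame(sample_id = ids,
                      water_fraction = stats::runif(n, config$water_range[1],
                                                    config$water_range[2]))

  # --- enteropathy markers (fecal wet basis + serum I-FABP) ---
  set.seed(derive_seed(config$seed, "markers"))
  mk <- cbind(
    calprotectin = 10^(2.48 + 0.35 * ii + stats::rnorm(n, 0, 0.40)),
    mpo          = 10^(3.60 + 0.35 * ii + stats::rnorm(n, 0, 0.40)),
    aat          = 10^(2.18 + 0.10 * ii + stats::rnorm(n, 0, 0.40)),
    ifabp        = 10^(2.90 + 0.15 * ii + stats::rnorm(n, 0, 0.35) +
                         config$ifabp_edema_effect * died * (!edema)))
  rownames(mk) <- ids
  markers <- analyte_matrix(
    mk,
    units = c(calprotectin = "ug/g wet", mpo = "ng/ml wet",
              aat = "ug/g wet", ifabp = "pg/ml serum"),
    analyte_class = setNames(rep("marker", 4), colnames(mk)),
    basis = "wet")

  # --- systemic analytes (serum) ---
  set.seed(derive_seed(config$seed, "systemic"))
  load_ind <- function(latent_score, k, base, scale_) {
    sapply(seq_len(k), function(j) {
      x <- 0.8 * latent_score + sqrt(1 - 0.64) * stats::rnorm(n)
      10^(base + scale_ * x)
    })
  }
  infl <- load_ind(si, 6, 1.5, 0.4)
  colnames(infl) <- c("IL7", "IL8", "IL15", "TNFa", "GCSF", "MCP1")
  scfa <- load_ind(cmp, 3, 1.0, 0.3)
  colnames(scfa) <- c("serum_propionate", "serum_butyrate", "serum_isobutyrate")
  sysm <- cbind(infl, scfa)
  rownames(sysm) <- ids
  systemic <- analyte_matrix(
    sysm,
    units = setNames(c(rep("pg/ml serum", 6), rep("umol/l serum", 3)),
                     colnames(sysm)),
    analyte_class = setNames(rep("marker", 9), colnames(sysm)),
    basis = "serum")

  truth <- list(differential = panel$differential,
                unstable = panel$unstable,
                low_detection = panel$low_detection,
                effect_log10 = eff,
                latent_paths = config$latent_paths,
                mortality_coef = config$mortality_coef,
                latent_scores = latent,
                mortality_prob = setNames(prob, ids))

  list(cohort = cohort(subjects),
       metabolome = metabolome,
       water = water,
       markers = markers,
       systemic = systemic,
       truth = truth)
}

#' Append QC replicate rows to an analyte matrix
#'
#' QC replicates are drawn around the pooled per-analyte median of the study
#' samples with multiplicative log-normal noise, then rescaled so the sample
#' coefficient of variation of the replicates equals the configured target
#' exactly (`qc_cv = 0` gives identical replicates). Pinning the sample CV,
#' rather than the population CV, makes the downstream QC filter's verdict a
#' deterministic function of the configuration: analytes designated unstable
#' get `qc_cv_unstable` and are removed whenever that target is at or above
#' the filter threshold.
#'
#' @param m an [analyte_matrix()] of study samples.
#' @param config a [sim_config()].
#' @return the matrix with `n_qc` additional rows flagged `is_qc`.
#' @export
simulate_qc_replicates <- function(m, config) {
  stopifnot(inherits(m, "analyte_matrix"), inherits(config, "sim_config"))
  p <- ncol(m$values)
  cvs <- setNames(rep(config$qc_cv, p), colnames(m$values))
  cvs[intersect(config_unstable(config, colnames(m$values)), names(cvs))] <-
    config$qc_cv_unstable
  ref <- apply(study_values(m), 2, stats::median, na.rm = TRUE)
  set.seed(derive_seed(config$seed, "qc"))
  qc <- sapply(seq_len(p), function(j) {
    if (cvs[j] == 0) return(rep(ref[j], config$n_qc))
    sigma <- sqrt(log(1 + cvs[j]^2))
    z <- stats::rnorm(config$n_qc)
    z <- (z - mean(z)) / stats::sd(z)
    x <- ref[j] * exp(sigma * z)
    # impose the target CV on the sample exactly
    x <- mean(x) + (x - mean(x)) * (cvs[j] * mean(x) / stats::sd(x))
    pmax(x, ref[j] * 1e-6)
  })
  qc <- matrix(qc, nrow = config$n_qc,
               dimnames = list(sprintf("qc%02d", seq_len(config$n_qc)),
                               colnames(m$values)))
  vals <- rbind(m$values, qc)
  analyte_matrix(vals, m$units, m$analyte_class, basis = m$basis,
                 is_qc = c(m$is_qc, setNames(rep(TRUE, config$n_qc), rownames(qc))))
}

# Unstable-analyte ids for a value matrix (panel ids when the matrix carries
# the generator's metabolite names, empty otherwise).
config_unstable <- function(config, analyte_ids) {
  panel <- metabolite_panel(config)
  if (all(panel$unstable %in% analyte_ids)) panel$unstable else character()
}

#' Simulate indicator data directly from a latent path structure
#'
#' Linear-Gaussian generator for parameter-recovery studies of the path
#' model: standardized latents follow the causal chain intestinal
#' inflammation -> luminal metabolism (negative), -> circulating microbial
#' products (positive) -> systemic inflammation (positive) -> mortality
#' (positive, continuous single indicator); each block's indicators load
#' equally on their latent.
#'
#' @param n number of subjects.
#' @param paths named coefficients `ii_lm`, `ii_cmp`, `cmp_si`, `si_mort`.
#' @param loading common indicator loading (default 0.8).
#' @param block_sizes named indicator counts for the II, LM, CMP, SI blocks.
#' @param seed integer seed.
#' @return list with `data` (indicator matrix), `spec` (the matching
#'   [path_model_spec()]) and `truth` (paths and latent scores).
#' @export
simulate_path_data <- function(n, paths = c(ii_lm = -0.4, ii_cmp = 0.5,
                                            cmp_si = 0.5, si_mort = 0.3),
                               loading = 0.8,
                               block_sizes = c(II = 2, LM = 15, CMP = 3, SI = 6),
                               seed = 1) {
  set.seed(derive_seed(seed, "path_data"))
  ii <- stats::rnorm(n)
  lm_ <- paths["ii_lm"] * ii + sqrt(1 - paths["ii_lm"]^2) * stats::rnorm(n)
  cmp <- paths["ii_cmp"] * ii + sqrt(1 - paths["ii_cmp"]^2) * stats::rnorm(n)
  si <- paths["cmp_si"] * cmp + sqrt(1 - paths["cmp_si"]^2) * stats::rnorm(n)
  mort <- paths["si_mort"] * si + sqrt(1 - paths["si_mort"]^2) * stats::rnorm(n)
  lat <- list(II = ii, LM = lm_, CMP = cmp, SI = si)
  blocks <- list()
  cols <- list()
  for (nm in names(block_sizes)) {
    k <- block_sizes[[nm]]
    nms <- sprintf("%s_x%02d", nm, seq_len(k))
    blocks[[nm]] <- nms
    cols[[nm]] <- sapply(seq_len(k), function(j) {
      loading * lat[[nm]] + sqrt(1 - loading^2) * stats::rnorm(n)
    })
    colnames(cols[[nm]]) <- nms
  }
  data <- cbind(do.call(cbind, cols), mortality = mort)
  ln <- c(names(block_sizes), "Mortality")
  blocks$Mortality <- "mortality"
  inner <- matrix(FALSE, 5, 5, dimnames = list(ln, ln))
  inner["LM", "II"] <- TRUE
  inner["CMP", "II"] <- TRUE
  inner["SI", "CMP"] <- TRUE
  inner["Mortality", "SI"] <- TRUE
  spec <- path_model_spec(blocks[ln], inner)
  list(data = data, spec = spec,
       truth = list(paths = paths, latent = lat, mortality = mort))
}
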