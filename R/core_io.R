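# Domain containers and table I/O shared by all pipeline stages.
#
# Design: plain-text CSV in and out (UTF-8, "." decimal, empty cell =
# missing); units carried as metadata strings and validated, never silently
# converted.  Containers are light S3 wrappers around data.frames/matrices in
# the style of clinical biostatistics packages.

GROUP_LEVELS <- c("case", "control", "unassigned")
HIV_LEVELS <- c("negative", "positive", "unknown")
ANALYTE_CLASSES <- c("SCFA", "carboxylic acid", "carbohydrate",
                     "amino acid and derivative", "alcohol", "other", "marker")

#' Construct a cohort of study subjects with optional matched pairs
#'
#' A cohort bundles the subject table (one row per child: demographic,
#' anthropometric and clinical covariates plus the case/control outcome
#' group) with a pair table recording 1:1 case-control matches.
#'
#' @param subjects data.frame with at least `subject_id`, `group`
#'   (`"case"` = nonsurvivor, `"control"` = survivor, `"unassigned"`),
#'   `age_months`, `muac_cm` and `hiv` (`"negative"`, `"positive"`,
#'   `"unknown"`). Further columns (edema, site, diarrhea, breastfed, sex,
#'   intervention arm, ...) are preserved as covariates.
#' @param pairs optional data.frame with columns `pair_id`, `case_id`,
#'   `control_id` (and optionally `distance`).
#' @return an object of class `cohort`.
#' @export
cohort <- function(subjects, pairs = NULL) {
  required <- c("subject_id", "group", "age_months", "muac_cm", "hiv")
  missing_cols <- setdiff(required, names(subjects))
  if (length(missing_cols) > 0) {
    stop_mm("mm_schema_error", "subject table is missing required column(s): %s",
            paste(missing_cols, collapse = ", "))
  }
  subjects$subject_id <- as.character(subjects$subject_id)
  if (anyDuplicated(subjects$subject_id)) {
    dup <- subjects$subject_id[duplicated(subjects$subject_id)][1]
    stop_mm("mm_integrity_error", "duplicate subject_id: %s", dup)
  }
  if (!all(subjects$group %in% GROUP_LEVELS)) {
    stop_mm("mm_schema_error", "group must be one of: %s",
            paste(GROUP_LEVELS, collapse = ", "))
  }
  if (!all(subjects$hiv %in% HIV_LEVELS)) {
    stop_mm("mm_schema_error", "hiv must be one of: %s",
            paste(HIV_LEVELS, collapse = ", "))
  }
  ok_age <- is.na(subjects$age_months) | subjects$age_months > 0
  ok_muac <- is.na(subjects$muac_cm) | subjects$muac_cm > 0
  if (!all(ok_age)) stop_mm("mm_schema_error", "age_months must be positive")
  if (!all(ok_muac)) stop_mm("mm_schema_error", "muac_cm must be positive")

  if (is.null(pairs)) {
    pairs <- data.frame(pair_id = character(), case_id = character(),
                        control_id = character(), stringsAsFactors = FALSE)
  }
  preq <- c("pair_id", "case_id", "control_id")
  if (!all(preq %in% names(pairs))) {
    stop_mm("mm_schema_error", "pair table needs columns: %s",
            paste(preq, collapse = ", "))
  }
  pairs$pair_id <- as.character(pairs$pair_id)
  pairs$case_id <- as.character(pairs$case_id)
  pairs$control_id <- as.character(pairs$control_id)
  members <- c(pairs$case_id, pairs$control_id)
  if (anyDuplicated(members)) {
    stop_mm("mm_integrity_error", "subject appears in more than one pair: %s",
            members[duplicated(members)][1])
  }
  if (!all(members %in% subjects$subject_id)) {
    stop_mm("mm_integrity_error", "pair member not in subject table: %s",
            setdiff(members, subjects$subject_id)[1])
  }
  if (nrow(pairs) > 0) {
    grp <- setNames(subjects$group, subjects$subject_id)
    if (!all(grp[pairs$case_id] == "case")) {
      stop_mm("mm_integrity_error", "every pair's case_id must have group 'case'")
    }
    if (!all(grp[pairs$control_id] == "control")) {
      stop_mm("mm_integrity_error", "every pair's control_id must have group 'control'")
    }
  }
  structure(list(subjects = subjects, pairs = pairs), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%d cases, %d controls), %d matched pairs\n",
              nrow(x$subjects), sum(x$subjects$group == "case"),
              sum(x$subjects$group == "control"), nrow(x$pairs)))
  invisible(x)
}

#' Read a cohort from delimited text
#'
#' @param path path to the subject table (CSV by default).
#' @param pairs_path optional path to a pair table.
#' @param sep field delimiter.
#' @return a [cohort()].
#' @export
read_cohort <- function(path, pairs_path = NULL, sep = ",") {
  subj <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  for (col in intersect(c("edema", "diarrhea", "breastfed"), names(subj))) {
    subj[[col]] <- as.logical(subj[[col]])
  }
  pairs <- if (!is.null(pairs_path)) {
    utils::read.csv(pairs_path, sep = sep, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
  }
  cohort(subj, pairs)
}

#' Write a cohort back to delimited text
#'
#' `write_cohort()` then [read_cohort()] reproduces the cohort; a second
#' round trip is byte-identical to the first.
#'
#' @param x a [cohort()].
#' @param path output path for the subject table.
#' @param pairs_path optional output path for the pair table.
#' @param sep field delimiter.
#' @export
write_cohort <- function(x, path, pairs_path = NULL, sep = ",") {
  stopifnot(inherits(x, "cohort"))
  utils::write.csv(x$subjects, path, row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(pairs_path)) {
    utils::write.csv(x$pairs, pairs_path, row.names = FALSE, quote = FALSE, na = "")
  }
  invisible(x)
}

#' Construct a samples-by-analytes concentration matrix
#'
#' Holds non-negative concentrations (NA = below detection / not measured)
#' together with per-analyte unit and class metadata, the measurement basis,
#' and a per-sample quality-control flag. QC replicate rows are excluded from
#' every group statistic downstream.
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids),
#'   analytes in columns (colnames = analyte ids).
#' @param units named character vector, one unit string per analyte.
#' @param analyte_class named character vector, one class per analyte; one of
#'   SCFA, carboxylic acid, carbohydrate, amino acid and derivative, alcohol,
#'   other, marker.
#' @param basis measurement basis: `"wet"`, `"dry"` or `"serum"`.
#' @param is_qc logical vector flagging QC replicate rows (default all FALSE).
#' @return an object of class `analyte_matrix`.
#' @export
analyte_matrix <- function(values, units, analyte_class,
                           basis = c("wet", "dry", "serum"), is_qc = NULL) {
  basis <- match.arg(basis)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop_mm("mm_schema_error", "values must have sample rownames and analyte colnames")
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop_mm("mm_schema_error", "concentrations must be non-negative or missing")
  }
  an <- colnames(values)
  units <- units[an]
  analyte_class <- analyte_class[an]
  if (anyNA(units)) stop_mm("mm_schema_error", "every analyte needs a unit")
  if (anyNA(analyte_class) || !all(analyte_class %in% ANALYTE_CLASSES)) {
    stop_mm("mm_schema_error", "every analyte needs a class in the allowed set")
  }
  if (is.null(is_qc)) is_qc <- rep(FALSE, nrow(values))
  stopifnot(length(is_qc) == nrow(values))
  is_qc <- setNames(as.logical(is_qc), rownames(values))
  structure(list(values = values, units = units, analyte_class = analyte_class,
                 basis = basis, is_qc = is_qc),
            class = "analyte_matrix")
}

#' @export
print.analyte_matrix <- function(x, ...) {
  cat(sprintf("<analyte_matrix> %d samples (%d QC) x %d analytes, basis=%s\n",
              nrow(x$values), sum(x$is_qc), ncol(x$values), x$basis))
  invisible(x)
}

# Study (non-QC) rows of an analyte matrix.
study_values <- function(m) m$values[!m$is_qc, , drop = FALSE]

#' Read an analyte matrix from a wide CSV plus an analyte metadata CSV
#'
#' The wide file holds one row per sample with a `sample_id` column, an
#' optional logical `is_qc` column, and one numeric column per analyte.
#' The companion file maps `analyte_id` to `class` and `unit`.
#'
#' @param values_path wide samples-by-analytes CSV.
#' @param analytes_path companion CSV with columns analyte_id, class, unit.
#' @param basis measurement basis of the stored concentrations.
#' @param sep field delimiter.
#' @return an [analyte_matrix()].
#' @export
read_analyte_matrix <- function(values_path, analytes_path,
                                basis = c("wet", "dry", "serum"), sep = ",") {
  basis <- match.arg(basis)
  wide <- utils::read.csv(values_path, sep = sep, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  meta <- utils::read.csv(analytes_path, sep = sep, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(wide)) {
    stop_mm("mm_schema_error", "wide table is missing required column: sample_id")
  }
  is_qc <- if ("is_qc" %in% names(wide)) as.logical(wide$is_qc) else rep(FALSE, nrow(wide))
  an_cols <- setdiff(names(wide), c("sample_id", "is_qc"))
  vals <- as.matrix(wide[, an_cols, drop = FALSE])
  rownames(vals) <- wide$sample_id
  missing_meta <- setdiff(an_cols, meta$analyte_id)
  if (length(missing_meta) > 0) {
    stop_mm("mm_schema_error", "analyte metadata missing for: %s",
            paste(missing_meta, collapse = ", "))
  }
  analyte_matrix(vals,
                 units = setNames(meta$unit, meta$analyte_id),
                 analyte_class = setNames(meta$class, meta$analyte_id),
                 basis = basis, is_qc = is_qc)
}

#' Write an analyte matrix to a wide CSV plus an analyte metadata CSV
#'
#' @param m an [analyte_matrix()].
#' @param values_path output path for the wide table.
#' @param analytes_path output path for the analyte metadata table.
#' @export
write_analyte_matrix <- function(m, values_path, analytes_path) {
  stopifnot(inherits(m, "analyte_matrix"))
  wide <- data.frame(sample_id = rownames(m$values),
                     is_qc = unname(m$is_qc),
                     m$values, check.names = FALSE)
  utils::write.csv(wide, values_path, row.names = FALSE, quote = FALSE, na = "")
  meta <- data.frame(analyte_id = colnames(m$values),
                     class = unname(m$analyte_class),
                     unit = unname(m$units))
  utils::write.csv(meta, analytes_path, row.names = FALSE, quote = FALSE, na = "")
  invisible(m)
}

#' Convert a wet-weight concentration to a dry-weight concentration
#'
#' Fecal analyte concentrations measured per gram of wet stool are
#' renormalized to the lyophilized (water-free) stool mass:
#' `dry = wet / (1 - water_fraction)`. Human feces are roughly 60-85% water,
#' so dry-weight values are typically 2.5-6.7 times the wet-weight values.
#'
#' @param conc_wet non-negative concentration per wet mass.
#' @param water_fraction fraction of sample mass that is water, in (0, 1).
#' @return concentration per dry mass.
#' @export
#' @examples
#' wet_to_dry(10, 0.75)  # 40
wet_to_dry <- function(conc_wet, water_fraction) {
  check_water_fraction(water_fraction)
  if (any(conc_wet < 0, na.rm = TRUE)) {
    stop_mm("mm_domain_error", "conc_wet must be non-negative")
  }
  conc_wet / (1 - water_fraction)
}

#' Convert a dry-weight concentration back to a wet-weight concentration
#'
#' Inverse of [wet_to_dry()].
#'
#' @param conc_dry non-negative concentration per dry mass.
#' @param water_fraction fraction of sample mass that is water, in (0, 1).
#' @return concentration per wet mass.
#' @export
dry_to_wet <- function(conc_dry, water_fraction) {
  check_water_fraction(water_fraction)
  if (any(conc_dry < 0, na.rm = TRUE)) {
    stop_mm("mm_domain_error", "conc_dry must be non-negative")
  }
  conc_dry * (1 - water_fraction)
}

check_water_fraction <- function(w) {
  if (any(!is.na(w) & (w <= 0 | w >= 1))) {
    stop_mm("mm_domain_error", "water_fraction must lie strictly in (0, 1)")
  }
  invisible(w)
}

#' Clinical cutoffs for enteropathy markers
#'
#' Reference cutoffs used to call marker levels elevated: fecal calprotectin
#' 200 ug/g wet feces, fecal myeloperoxidase (MPO) 2000 ng/ml wet feces,
#' fecal alpha-1-antitrypsin (AAT) 270 ug/g wet feces, and serum I-FABP
#' 450 pg/ml. All overridable.
#'
#' @param calprotectin_wet,mpo_wet,aat_wet,ifabp_serum positive cutoffs.
#' @return named list of cutoffs with the unit each is defined in.
#' @export
clinical_cutoffs <- function(calprotectin_wet = 200, mpo_wet = 2000,
                             aat_wet = 270, ifabp_serum = 450) {
  vals <- c(calprotectin = calprotectin_wet, mpo = mpo_wet,
            aat = aat_wet, ifabp = ifabp_serum)
  if (any(vals <= 0)) stop_mm("mm_domain_error", "cutoffs must be strictly positive")
  structure(list(
    cutoff = vals,
    unit = c(calprotectin = "ug/g wet", mpo = "ng/ml wet",
             aat = "ug/g wet", ifabp = "pg/ml serum")
  ), class = "clinical_cutoffs")
}

#' Flag marker exceedance against clinical cutoffs
#'
#' Compares wet-weight fecal marker concentrations (and serum I-FABP) to
#' clinical cutoffs. A value counts as elevated only when strictly above the
#' cutoff; values exactly at the cutoff are not elevated. Per-group
#' proportions use non-missing values as the denominator, with missingness
#' counts reported alongside.
#'
#' @param markers an [analyte_matrix()] of marker concentrations whose
#'   analyte ids match the cutoff names (`calprotectin`, `mpo`, `aat`,
#'   `ifabp`).
#' @param cutoffs a [clinical_cutoffs()] object.
#' @param group named character vector (by sample id) of group labels.
#' @return list with `elevated` (samples x markers logical matrix) and
#'   `proportions` (data.frame of per-group elevated proportions and counts).
#' @export
flag_exceedance <- function(markers, cutoffs, group) {
  stopifnot(inherits(markers, "analyte_matrix"), inherits(cutoffs, "clinical_cutoffs"))
  ids <- intersect(colnames(markers$values), names(cutoffs$cutoff))
  if (length(ids) == 0) stop_mm("mm_schema_error", "no marker matches a cutoff name")
  for (id in ids) {
    if (!identical(unname(markers$units[id]), unname(cutoffs$unit[id]))) {
      stop_mm("mm_unit_error",
              "unit mismatch for %s: matrix has '%s', cutoff is defined per '%s'",
              id, markers$units[id], cutoffs$unit[id])
    }
  }
  vals <- study_values(markers)[, ids, drop = FALSE]
  elevated <- sweep(vals, 2, cutoffs$cutoff[ids], `>`)
  grp <- group[rownames(vals)]
  rows <- list()
  for (g in unique(grp[!is.na(grp)])) {
    sub <- elevated[grp == g & !is.na(grp), , drop = FALSE]
    for (id in ids) {
      n_obs <- sum(!is.na(sub[, id]))
      rows[[length(rows) + 1]] <- data.frame(
        group = g, marker = id,
        n_elevated = sum(sub[, id], na.rm = TRUE),
        n_observed = n_obs,
        n_missing = nrow(sub) - n_obs,
        proportion = if (n_obs > 0) sum(sub[, id], na.rm = TRUE) / n_obs else NA_real_
      )
    }
  }
  list(elevated = elevated, proportions = do.call(rbind, rows))
}
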