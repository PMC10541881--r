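# Analyte quality filtering, detection-rate filtering, imputation,
# transformation and class-level summaries of the metabolite matrix.
#
# Retention rule: an analyte is kept iff its coefficient of variation over QC
# replicates is strictly below 0.30 AND it is detected (non-missing) in at
# least 80% of samples in at least one of the two groups.

#' Quality-control coefficient-of-variation filter
#'
#' Computes, per analyte, the coefficient of variation (sample sd / mean, on
#' the raw concentration scale) over the QC replicate rows. Analytes are
#' retained iff CV < 0.30 strictly; a CV of exactly 0.30 is removed.
#'
#' @param m an [analyte_matrix()] containing at least two QC replicate rows.
#' @param cv_max retention threshold (default 0.30, strict).
#' @return data.frame with columns analyte_id, qc_cv, retained_qc.
#' @export
qc_cv_filter <- function(m, cv_max = 0.30) {
  stopifnot(inherits(m, "analyte_matrix"))
  qc <- m$values[m$is_qc, , drop = FALSE]
  if (nrow(qc) < 2) {
    stop_mm("mm_domain_error", "need at least 2 QC replicates to compute a CV")
  }
  cv <- apply(qc, 2, coef_variation)
  data.frame(analyte_id = colnames(m$values),
             qc_cv = as.numeric(cv),
             retained_qc = !is.na(cv) & cv < cv_max,
             row.names = NULL)
}

#' Group-wise detection-rate filter
#'
#' Detection rate is the non-missing fraction among study (non-QC) samples of
#' each group. An analyte is retained iff its detection rate reaches at least
#' `rate_min` (default 0.80, inclusive) in the case group OR in the control
#' group.
#'
#' @param m an [analyte_matrix()].
#' @param group named character vector of `"case"`/`"control"` labels by
#'   sample id.
#' @param rate_min retention threshold (default 0.80, inclusive).
#' @return data.frame with detection rates per group and retained_detection.
#' @export
detection_filter <- function(m, group, rate_min = 0.80) {
  stopifnot(inherits(m, "analyte_matrix"))
  vals <- study_values(m)
  grp <- group[rownames(vals)]
  rate_for <- function(g) {
    sub <- vals[!is.na(grp) & grp == g, , drop = FALSE]
    if (nrow(sub) == 0) return(rep(NA_real_, ncol(vals)))
    colMeans(!is.na(sub))
  }
  rc <- rate_for("case"); rs <- rate_for("control")
  data.frame(analyte_id = colnames(vals),
             detection_case = as.numeric(rc),
             detection_control = as.numeric(rs),
             retained_detection = pmax(rc, rs, na.rm = TRUE) >= rate_min,
             row.names = NULL)
}

#' Combined quality filter report
#'
#' Joins the QC-CV and detection filters; an analyte is retained iff it
#' passes both. Order of the two filters does not matter.
#'
#' @inheritParams detection_filter
#' @param cv_max,rate_min thresholds passed to the component filters.
#' @return data.frame (one row per analyte) with both filters' columns, the
#'   combined `retained` flag and a human-readable `reason` for removal.
#' @export
filter_report <- function(m, group, cv_max = 0.30, rate_min = 0.80) {
  qc <- qc_cv_filter(m, cv_max)
  det <- detection_filter(m, group, rate_min)
  rep <- merge(qc, det, by = "analyte_id", sort = FALSE)
  rep$retained <- rep$retained_qc & rep$retained_detection
  rep$reason <- ifelse(rep$retained, "",
                ifelse(!rep$retained_qc & !rep$retained_detection, "qc_cv;detection",
                ifelse(!rep$retained_qc, "qc_cv", "detection")))
  # keep the matrix column order
  rep[match(colnames(m$values), rep$analyte_id), , drop = FALSE]
}

#' Drop analytes flagged for removal
#'
#' @param m an [analyte_matrix()].
#' @param report output of [filter_report()].
#' @return the matrix restricted to retained analytes.
#' @export
apply_filter <- function(m, report) {
  keep <- report$analyte_id[report$retained]
  analyte_matrix(m$values[, keep, drop = FALSE], m$units[keep],
                 m$analyte_class[keep], basis = m$basis, is_qc = m$is_qc)
}

#' Impute below-detection values by half the observed minimum
#'
#' Each missing value of an analyte is replaced by half the minimum observed
#' value of that analyte over all study (non-QC) samples — the conventional
#' left-censoring surrogate for values below the detection limit. Observed
#' values are never changed; the imputation mask is kept for audit.
#'
#' @param m an [analyte_matrix()] (already filtered).
#' @return the matrix with no missing study values and attribute
#'   `imputation_mask` (logical matrix of imputed cells).
#' @export
impute_missing <- function(m) {
  stopifnot(inherits(m, "analyte_matrix"))
  vals <- m$values
  study <- !m$is_qc
  mask <- is.na(vals) & study
  for (j in seq_len(ncol(vals))) {
    miss <- mask[, j]
    if (!any(miss)) next
    obs <- vals[study, j]
    obs <- obs[!is.na(obs)]
    if (length(obs) == 0) {
      stop_mm("mm_domain_error",
              "analyte %s has no observed study values; it should have been filtered",
              colnames(vals)[j])
    }
    vals[miss, j] <- min(obs) / 2
  }
  out <- analyte_matrix(vals, m$units, m$analyte_class, basis = m$basis,
                        is_qc = m$is_qc)
  attr(out, "imputation_mask") <- mask
  out
}

#' Log10 transform and optional per-analyte z-scoring
#'
#' Concentrations are log10-transformed for modeling; multivariable stages
#' additionally standardize each analyte to mean 0, sd 1. Zero-variance
#' analytes cannot be z-scored and are dropped with a warning.
#'
#' @param m an [analyte_matrix()] with strictly positive values
#'   (post-imputation).
#' @param standardize if TRUE, z-score each analyte over study samples.
#' @return numeric matrix of transformed study (non-QC) sample values.
#' @export
transform_standardize <- function(m, standardize = FALSE) {
  stopifnot(inherits(m, "analyte_matrix"))
  vals <- study_values(m)
  bad <- which(vals <= 0 | is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_mm("mm_domain_error",
            "non-positive or missing value for sample %s, analyte %s; impute first",
            rownames(vals)[bad[1, 1]], colnames(vals)[bad[1, 2]])
  }
  lv <- log10(vals)
  if (!standardize) return(lv)
  sds <- apply(lv, 2, stats::sd)
  if (any(sds == 0)) {
    drop <- colnames(lv)[sds == 0]
    warning(sprintf("dropping zero-variance analyte(s): %s",
                    paste(drop, collapse = ", ")))
    lv <- lv[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  scale(lv, center = TRUE, scale = TRUE)[, , drop = FALSE]
}

#' Class-level totals, proportions and group summaries
#'
#' Per-sample class totals are sums of raw (untransformed) concentrations
#' over member analytes, intended for dry-weight data; per-sample relative
#' proportions sum to 1; group means and sds are reported per class.
#'
#' @param m an [analyte_matrix()].
#' @param group named character vector of group labels by sample id.
#' @return list with `totals` (samples x classes), `proportions`
#'   (samples x classes, rows sum to 1) and `group_summary` (data.frame of
#'   per-class, per-group mean and sd of the totals).
#' @export
class_summaries <- function(m, group = NULL) {
  stopifnot(inherits(m, "analyte_matrix"))
  vals <- study_values(m)
  classes <- sort(unique(unname(m$analyte_class)))
  totals <- sapply(classes, function(cl) {
    member <- names(m$analyte_class)[m$analyte_class == cl]
    rowSums(vals[, member, drop = FALSE], na.rm = TRUE)
  })
  totals <- matrix(totals, nrow = nrow(vals),
                   dimnames = list(rownames(vals), classes))
  props <- totals / rowSums(totals)
  summ <- NULL
  if (!is.null(group)) {
    grp <- group[rownames(vals)]
    rows <- list()
    for (g in unique(grp[!is.na(grp)])) {
      sub <- totals[!is.na(grp) & grp == g, , drop = FALSE]
      rows[[g]] <- data.frame(group = g, class = classes,
                              mean = colMeans(sub),
                              sd = apply(sub, 2, stats::sd),
                              row.names = NULL)
    }
    summ <- do.call(rbind, c(rows, make.row.names = FALSE))
  }
  list(totals = totals, proportions = props, group_summary = summ)
}
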