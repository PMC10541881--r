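# Propensity-score estimation and 1:1 nearest-neighbor matching of survivors
# (controls) to nonsurvivors (cases).

#' Fit a propensity score model for mortality
#'
#' Maximum-likelihood logistic regression of death on the three matching
#' covariates: age (months), MUAC (cm) and HIV status. HIV enters as two
#' indicators (positive, unknown) against the negative reference, so the
#' unknown/refused stratum is kept as its own level.
#'
#' @param cohort a [cohort()] whose `group` column encodes the outcome
#'   (`case` = died, `control` = survived); subjects with group
#'   `"unassigned"` are excluded from the fit.
#' @return object of class `propensity_model` with elements `coefficients`,
#'   `scores` (named per-subject probabilities in (0,1)) and the underlying
#'   `glm` fit.
#' @export
fit_propensity <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  s <- cohort$subjects
  s <- s[s$group %in% c("case", "control"), , drop = FALSE]
  if (anyNA(s$age_months) || anyNA(s$muac_cm) || anyNA(s$hiv)) {
    stop_mm("mm_domain_error", "matching covariates must be non-missing")
  }
  s$hiv <- droplevels(factor(s$hiv, levels = HIV_LEVELS))
  s$died <- as.integer(s$group == "case")
  # covariates without variation carry no information and would break the
  # model matrix; with none left the score is the marginal death rate
  covs <- c("age_months", "muac_cm", "hiv")
  covs <- covs[vapply(covs, function(cl) length(unique(s[[cl]])) > 1, logical(1))]
  form <- if (length(covs) > 0) stats::reformulate(covs, "died") else died ~ 1
  fit <- stats::glm(form, data = s, family = stats::binomial())
  if (!fit$converged || any(abs(stats::coef(fit)) > 15, na.rm = TRUE)) {
    stop_mm("mm_separation_error",
            "propensity model did not converge to finite coefficients (possible complete separation); consider a penalized fit")
  }
  scores <- stats::predict(fit, type = "response")
  structure(list(coefficients = stats::coef(fit),
                 scores = setNames(as.numeric(scores), s$subject_id),
                 fit = fit),
            class = "propensity_model")
}

#' Greedy 1:1 nearest-neighbor matching on the propensity score
#'
#' Cases are processed in descending propensity-score order; each is paired
#' with the unused control minimizing the absolute score difference
#' (optionally within a caliper), without replacement. Ties between controls
#' are broken by lexical order of the control identifier, so matching is
#' deterministic.
#'
#' @param model a `propensity_model` from [fit_propensity()].
#' @param cohort the [cohort()] to match.
#' @param caliper optional maximum allowed absolute score distance.
#' @return the cohort with its `pairs` table filled (columns pair_id,
#'   case_id, control_id, distance) and an `unmatched` attribute listing
#'   case ids that found no admissible control.
#' @export
match_pairs <- function(model, cohort, caliper = NULL) {
  stopifnot(inherits(model, "propensity_model"), inherits(cohort, "cohort"))
  s <- cohort$subjects
  case_ids <- s$subject_id[s$group == "case"]
  control_ids <- s$subject_id[s$group == "control"]
  if (length(control_ids) == 0) stop_mm("mm_matching_error", "control pool is empty")
  sc <- model$scores
  if (!all(c(case_ids, control_ids) %in% names(sc))) {
    stop_mm("mm_matching_error", "propensity scores missing for some subjects")
  }
  # descending score order; case-id order breaks score ties deterministically
  case_ids <- case_ids[order(-sc[case_ids], case_ids)]
  available <- sort(control_ids)
  rows <- vector("list", length(case_ids))
  unmatched <- character()
  k <- 0
  for (cid in case_ids) {
    if (length(available) == 0) { unmatched <- c(unmatched, cid); next }
    d <- abs(sc[available] - sc[cid])
    best <- available[which.min(d)]   # ties: first in lexical order
    bestd <- min(d)
    if (!is.null(caliper) && bestd > caliper) { unmatched <- c(unmatched, cid); next }
    k <- k + 1
    rows[[k]] <- data.frame(pair_id = sprintf("p%03d", k), case_id = cid,
                            control_id = best, distance = as.numeric(bestd))
    available <- setdiff(available, best)
  }
  pairs <- if (k > 0) do.call(rbind, rows[seq_len(k)]) else NULL
  out <- cohort(s, pairs)
  attr(out, "unmatched") <- unmatched
  out
}

#' Standardized mean differences of the matching covariates
#'
#' Balance diagnostic: (mean_case - mean_control) / pooled sd for age, MUAC
#' and the HIV indicators, computed either over all subjects or over matched
#' pairs only.
#'
#' @param cohort a [cohort()].
#' @param matched_only if TRUE restrict to subjects appearing in pairs.
#' @return named numeric vector of standardized mean differences.
#' @export
covariate_balance <- function(cohort, matched_only = FALSE) {
  s <- cohort$subjects
  if (matched_only) {
    keep <- c(cohort$pairs$case_id, cohort$pairs$control_id)
    s <- s[s$subject_id %in% keep, , drop = FALSE]
  } else {
    s <- s[s$group %in% c("case", "control"), , drop = FALSE]
  }
  x <- cbind(age_months = s$age_months, muac_cm = s$muac_cm,
             hiv_positive = as.numeric(s$hiv == "positive"),
             hiv_unknown = as.numeric(s$hiv == "unknown"))
  g <- s$group == "case"
  smd <- apply(x, 2, function(col) {
    m1 <- mean(col[g]); m0 <- mean(col[!g])
    sp <- sqrt((stats::var(col[g]) + stats::var(col[!g])) / 2)
    if (sp == 0) 0 else (m1 - m0) / sp
  })
  smd
}
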