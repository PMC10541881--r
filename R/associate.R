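# Univariate matched and adjusted association analyses: 1:1 conditional
# logistic regression, BH-FDR, 2x2 odds ratios with Woolf intervals,
# IQR-scaled odds ratios, covariate-adjusted logistic models with
# interaction tests, and FDR-screened pairwise Pearson correlations.

#' Case-minus-control differences over matched pairs
#'
#' @param values named numeric vector of per-subject analyte values on the
#'   analysis scale (log10 for metabolites).
#' @param pairs pair table with columns pair_id, case_id, control_id.
#' @return data.frame with pair_id and difference (case - control).
#' @export
paired_differences <- function(values, pairs) {
  if (!all(c(pairs$case_id, pairs$control_id) %in% names(values))) {
    stop_mm("mm_domain_error", "values missing for some pair members")
  }
  d <- values[pairs$case_id] - values[pairs$control_id]
  if (any(!is.finite(d))) stop_mm("mm_domain_error", "non-finite pair difference")
  data.frame(pair_id = pairs$pair_id, difference = as.numeric(d))
}

#' Conditional logistic regression for 1:1 matched pairs
#'
#' Maximizes the pair-conditional likelihood
#' \eqn{\prod_i \exp(\beta d_i)/(1+\exp(\beta d_i))} over the case-minus-
#' control differences \eqn{d_i}, which is identical to intercept-free
#' logistic regression of a constant-1 response on the differences. The
#' estimate is therefore invariant to adding any constant to both members of
#' a pair. Wald two-sided p-values and exponentiated 95% confidence limits
#' are reported.
#'
#' @param values named numeric vector of per-subject values (analysis scale).
#' @param pairs pair table with columns pair_id, case_id, control_id.
#' @param conf_level confidence level for the Wald interval.
#' @return one-row data.frame: estimate (log-odds per unit), se, or_,
#'   ci_low, ci_high, p.
#' @export
conditional_logit_1to1 <- function(values, pairs, conf_level = 0.95) {
  d <- paired_differences(values, pairs)$difference
  if (all(d == 0)) {
    stop_mm("mm_domain_error", "all pair differences are zero (zero-variance analyte)")
  }
  if (all(d >= 0) || all(d <= 0)) {
    stop_mm("mm_separation_error",
            "all nonzero pair differences share one sign; the conditional MLE is infinite")
  }
  y <- rep(1L, length(d))
  fit <- stats::glm(y ~ d - 1, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  est <- unname(stats::coef(fit)["d"])
  se <- sqrt(stats::vcov(fit)["d", "d"])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  p <- 2 * stats::pnorm(-abs(est / se))
  data.frame(estimate = est, se = se, or_ = exp(est),
             ci_low = exp(est - z * se), ci_high = exp(est + z * se), p = p)
}

#' Matched univariate screen of an analyte matrix
#'
#' Runs [conditional_logit_1to1()] per analyte on log10 concentrations and
#' appends Benjamini-Hochberg adjusted p-values. Analytes whose conditional
#' MLE does not exist (zero variance or complete separation) are reported
#' with NA statistics rather than dropped.
#'
#' @param X numeric matrix of study samples x analytes on the analysis scale
#'   (e.g. output of [transform_standardize()] without z-scoring).
#' @param pairs pair table.
#' @param conf_level Wald interval level.
#' @return data.frame, one row per analyte: estimate, se, or_, ci_low,
#'   ci_high, p, p_adj.
#' @export
univariate_screen <- function(X, pairs, conf_level = 0.95) {
  res <- lapply(colnames(X), function(an) {
    row <- tryCatch(
      conditional_logit_1to1(setNames(X[, an], rownames(X)), pairs, conf_level),
      metabmort_error = function(e) data.frame(estimate = NA_real_, se = NA_real_,
                                               or_ = NA_real_, ci_low = NA_real_,
                                               ci_high = NA_real_, p = NA_real_))
    cbind(analyte_id = an, row)
  })
  out <- do.call(rbind, res)
  out$p_adj <- bh_fdr(out$p)
  out
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment with enforced monotonicity; input order preserved.
#' NA p-values propagate as NA without affecting the other adjustments.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop_mm("mm_domain_error", "p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' 2x2 odds ratio with Woolf confidence interval
#'
#' For exposure counts a/b (case exposed/unexposed) and c/d (control
#' exposed/unexposed): OR = ad/bc with log-scale normal interval
#' \eqn{\exp(\ln OR \pm z \sqrt{1/a+1/b+1/c+1/d})}. A zero cell triggers
#' the Haldane-Anscombe 0.5 continuity correction on all cells (flagged in
#' the output), or an error when `strict = TRUE`.
#'
#' @param a,b,c,d non-negative integer counts.
#' @param conf_level confidence level.
#' @param strict error on zero cells instead of correcting.
#' @return one-row data.frame: or_, ci_low, ci_high, corrected.
#' @export
#' @examples
#' odds_ratio_2x2(29, 39, 16, 52)  # edema among nonsurvivors vs survivors
odds_ratio_2x2 <- function(a, b, c, d, conf_level = 0.95, strict = FALSE) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop_mm("mm_domain_error", "cells must be non-negative counts")
  }
  corrected <- FALSE
  if (any(cells == 0)) {
    if (strict) stop_mm("mm_domain_error", "zero cell in 2x2 table (strict mode)")
    cells <- cells + 0.5
    corrected <- TRUE
  }
  or_ <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(or_ = or_, ci_low = exp(log(or_) - z * se),
             ci_high = exp(log(or_) + z * se), corrected = corrected)
}

#' Odds ratio for an interquartile-range increase
#'
#' Rescales a per-unit log-odds estimate to the odds ratio associated with
#' moving from the 25th to the 75th percentile of the analyte, expressed on
#' the model's analysis scale: \eqn{OR_{IQR} = \exp(\beta \Delta)} with
#' \eqn{\Delta} the q25-to-q75 change on that scale.
#'
#' @param estimate per-unit log-odds (analysis scale).
#' @param q25,q75 quartiles on the raw concentration scale.
#' @param se optional standard error, for a rescaled confidence interval.
#' @param log10_scale if TRUE the analysis scale is log10 concentration, so
#'   the change is `log10(q75) - log10(q25)`; otherwise `q75 - q25`.
#' @param conf_level confidence level.
#' @return one-row data.frame: or_iqr (and ci_low/ci_high when se given).
#' @export
iqr_scaled_or <- function(estimate, q25, q75, se = NULL, log10_scale = TRUE,
                          conf_level = 0.95) {
  if (q75 <= q25) stop_mm("mm_domain_error", "q75 must exceed q25")
  delta <- if (log10_scale) log10(q75) - log10(q25) else q75 - q25
  out <- data.frame(or_iqr = exp(estimate * delta))
  if (!is.null(se)) {
    z <- stats::qnorm(1 - (1 - conf_level) / 2)
    out$ci_low <- exp((estimate - z * se) * delta)
    out$ci_high <- exp((estimate + z * se) * delta)
  }
  out
}

#' Covariate-adjusted logistic regression for an unpaired marker
#'
#' Unconditional maximum-likelihood logistic regression of case status on a
#' marker, adjusted for the matching covariates (age, MUAC, HIV), for
#' markers like serum I-FABP where unpaired samples would otherwise be
#' dropped. Optionally adds an edema main effect and marker-by-edema
#' interaction, reporting the Wald p of the product term and the stratified
#' marker odds ratios implied by the fit.
#'
#' @param data data.frame with columns `died` (0/1), `marker`, `age_months`,
#'   `muac_cm`, `hiv`, and `edema` when `edema_interaction = TRUE`.
#' @param edema_interaction include the marker x edema interaction.
#' @param conf_level confidence level.
#' @return list with `marker` (one-row data.frame: estimate, se, or_,
#'   ci_low, ci_high, p), the `glm` `fit`, and when requested
#'   `interaction_p` plus `stratified` per-stratum marker effects.
#' @export
adjusted_logistic <- function(data, edema_interaction = FALSE, conf_level = 0.95) {
  req <- c("died", "marker", "age_months", "muac_cm", "hiv")
  if (!all(req %in% names(data))) {
    stop_mm("mm_schema_error", "data needs columns: %s", paste(req, collapse = ", "))
  }
  data$hiv <- droplevels(factor(data$hiv, levels = HIV_LEVELS))
  # constant covariates carry no information and would break the model matrix
  adj <- c("age_months", "muac_cm", "hiv")
  keep <- vapply(adj, function(cl) length(unique(data[[cl]])) > 1, logical(1))
  rhs <- c(if (edema_interaction) "marker * edema" else "marker", adj[keep])
  form <- stats::reformulate(rhs, response = "died")
  fit <- stats::glm(form, data = data, family = stats::binomial())
  if (any(abs(stats::coef(fit)) > 20, na.rm = TRUE)) {
    warning("very large coefficients: possible separation; consider a penalized fit")
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  wald_row <- function(est, se) {
    data.frame(estimate = est, se = se, or_ = exp(est),
               ci_low = exp(est - z * se), ci_high = exp(est + z * se),
               p = 2 * stats::pnorm(-abs(est / se)))
  }
  cf <- stats::coef(fit); V <- stats::vcov(fit)
  out <- list(marker = wald_row(cf["marker"], sqrt(V["marker", "marker"])),
              fit = fit)
  if (edema_interaction) {
    it <- grep("^marker:", names(cf), value = TRUE)
    out$interaction_p <- 2 * stats::pnorm(-abs(cf[it] / sqrt(V[it, it])))
    # stratified effects: non-edema slope is the marker term; edema slope adds
    # the product term, with variance from the delta method
    b1 <- cf["marker"]; b3 <- cf[it]
    se0 <- sqrt(V["marker", "marker"])
    se1 <- sqrt(V["marker", "marker"] + V[it, it] + 2 * V["marker", it])
    out$stratified <- rbind(cbind(stratum = "non-edema", wald_row(b1, se0)),
                            cbind(stratum = "edema", wald_row(b1 + b3, se1)))
  }
  out
}

#' Pairwise Pearson correlations with BH-FDR screening
#'
#' Computes the Pearson correlation for every unordered analyte pair over
#' complete observations, the two-sided p-value from the t transform
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}}, and a Benjamini-Hochberg adjustment
#' across all unique pairs; the significance mask is `p_adj < alpha`.
#' Constant columns yield undefined correlations, reported as NA.
#'
#' @param X numeric matrix, samples x analytes.
#' @param alpha FDR threshold for the significance mask.
#' @return list with symmetric matrices `r`, `p`, `p_adj` (unit diagonal,
#'   NA p on the diagonal) and logical `significant`.
#' @export
pairwise_pearson_fdr <- function(X, alpha = 0.05) {
  p_ <- ncol(X)
  an <- colnames(X)
  r <- matrix(NA_real_, p_, p_, dimnames = list(an, an))
  pv <- r
  diag(r) <- 1
  idx <- which(upper.tri(r), arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    ok <- stats::complete.cases(X[, i], X[, j])
    n <- sum(ok)
    if (n < 3) next
    xi <- X[ok, i]; xj <- X[ok, j]
    if (stats::sd(xi) == 0 || stats::sd(xj) == 0) next
    rho <- stats::cor(xi, xj)
    r[i, j] <- r[j, i] <- rho
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    pv[i, j] <- pv[j, i] <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  padj_vec <- bh_fdr(pv[upper.tri(pv)])
  p_adj <- pv
  p_adj[upper.tri(p_adj)] <- padj_vec
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  list(r = r, p = pv, p_adj = p_adj,
       significant = !is.na(p_adj) & p_adj < alpha)
}
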