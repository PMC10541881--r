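# Multilevel (within-pair) partial least squares discriminant analysis of the
# differential feature profile, with pair-grouped cross-validated AUC and
# misclassification rate.
#
# The PLS2 extraction is implemented here directly (NIPALS with X- and
# Y-deflation); installed PLS-DA packages serve only as independent
# cross-checks in the test suite.

#' Within-pair (multilevel) decomposition of a paired data matrix
#'
#' Removes between-pair variation: `X_within = X - pair_means + grand_mean`.
#' Every sample must belong to exactly one pair. The within and between
#' parts reconstruct X exactly: `X = X_within + X_between - grand_mean`.
#'
#' @param X numeric matrix with sample ids as rownames.
#' @param pairs pair table with case_id/control_id columns.
#' @return matrix of within-pair deviations (same dimensions, pair-mean rows
#'   equal the grand mean), with attribute `between` holding the pair-mean
#'   matrix.
#' @export
multilevel_decompose <- function(X, pairs) {
  members <- c(pairs$case_id, pairs$control_id)
  if (!all(rownames(X) %in% members)) {
    stop_mm("mm_domain_error", "unpaired sample(s): %s",
            paste(head(setdiff(rownames(X), members), 3), collapse = ", "))
  }
  pair_of <- setNames(rep(pairs$pair_id, 2), members)[rownames(X)]
  grand <- colMeans(X)
  pm <- apply(X, 2, function(col) tapply(col, pair_of, mean))
  between <- pm[pair_of, , drop = FALSE]
  rownames(between) <- rownames(X)
  within <- X - between + matrix(grand, nrow(X), ncol(X), byrow = TRUE)
  attr(within, "between") <- between
  within
}

#' Fit a PLS-DA model by NIPALS
#'
#' PLS2 regression of a one-hot class indicator matrix on X: components are
#' extracted to maximize covariance with the class indicators, deflating X
#' and Y after each. Weights are unit-norm and successive score vectors are
#' mutually orthogonal. Class prediction uses the maximum predicted class
#' score, with ties broken toward `"control"`.
#'
#' @param X numeric predictor matrix (samples x features), typically the
#'   standardized within-pair deviations.
#' @param y factor or character vector of class labels (two classes).
#' @param n_components number of latent components (default 2).
#' @param tol NIPALS convergence tolerance.
#' @param max_iter NIPALS iteration cap.
#' @return object of class `plsda_model` with weights `W`, loadings `P`,
#'   y-loadings `C`, scores `T_scores`, centering/scaling vectors and class
#'   levels.
#' @export
plsda_fit <- function(X, y, n_components = 2, tol = 1e-10, max_iter = 500) {
  y <- as.factor(y)
  if (nlevels(y) != 2) stop_mm("mm_domain_error", "exactly two classes required")
  if (n_components > min(nrow(X) - 1, ncol(X))) {
    stop_mm("mm_domain_error", "n_components exceeds the rank of X")
  }
  x_center <- colMeans(X)
  x_scale <- apply(X, 2, stats::sd)
  if (any(x_scale == 0)) stop_mm("mm_domain_error", "zero-variance feature in X")
  Xc <- scale(X, center = x_center, scale = x_scale)
  Y <- stats::model.matrix(~ y - 1)
  colnames(Y) <- levels(y)
  y_center <- colMeans(Y)
  Yc <- scale(Y, center = TRUE, scale = FALSE)

  p_ <- ncol(Xc); q_ <- ncol(Yc); n_ <- nrow(Xc)
  W <- matrix(0, p_, n_components); P <- matrix(0, p_, n_components)
  C <- matrix(0, q_, n_components); T_scores <- matrix(0, n_, n_components)
  Xd <- Xc; Yd <- Yc
  for (h in seq_len(n_components)) {
    u <- Yd[, which.max(apply(Yd, 2, stats::var))]
    t_old <- rep(Inf, n_)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u)
      w <- w / sqrt(sum(w^2))
      t_ <- Xd %*% w
      cc <- crossprod(Yd, t_) / sum(t_^2)
      u <- Yd %*% cc / sum(cc^2)
      if (sqrt(sum((t_ - t_old)^2)) < tol) break
      t_old <- t_
    }
    pl <- crossprod(Xd, t_) / sum(t_^2)
    Xd <- Xd - tcrossprod(t_, pl)
    Yd <- Yd - tcrossprod(t_, cc)
    W[, h] <- w; P[, h] <- pl; C[, h] <- cc; T_scores[, h] <- t_
  }
  rownames(W) <- rownames(P) <- colnames(X)
  rownames(T_scores) <- rownames(X)
  structure(list(W = W, P = P, C = C, T_scores = T_scores,
                 x_center = x_center, x_scale = x_scale, y_center = y_center,
                 levels = levels(y), n_components = n_components),
            class = "plsda_model")
}

#' Predict class scores and classes from a PLS-DA model
#'
#' @param object a `plsda_model`.
#' @param newdata matrix on the original feature scale.
#' @param ... unused.
#' @return list with `scores` (component scores), `class_scores` (predicted
#'   class-indicator values) and `class` (argmax decision, ties toward the
#'   control/first level).
#' @export
predict.plsda_model <- function(object, newdata, ...) {
  Xc <- scale(newdata, center = object$x_center, scale = object$x_scale)
  R <- object$W %*% solve(crossprod(object$P, object$W))   # projection weights
  Tn <- Xc %*% R
  Yhat <- Tn %*% t(object$C) +
    matrix(object$y_center, nrow(Xc), length(object$y_center), byrow = TRUE)
  colnames(Yhat) <- object$levels
  cls <- apply(Yhat, 1, function(r) {
    ctrl <- match("control", object$levels)
    if (is.na(ctrl)) ctrl <- 1
    if (abs(r[1] - r[2]) < 1e-12) object$levels[ctrl] else object$levels[which.max(r)]
  })
  list(scores = Tn, class_scores = Yhat, class = cls)
}

#' AUC by the rank-sum formula
#'
#' Probability that a randomly chosen case scores higher than a randomly
#' chosen control, computed from midranks (ties count one half); equals the
#' proportion of concordant case-control score pairs.
#'
#' @param score numeric predicted score (higher = more case-like).
#' @param is_case logical or 0/1 indicator.
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(score, is_case) {
  is_case <- as.logical(is_case)
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 == 0 || n0 == 0) stop_mm("mm_domain_error", "need both classes for AUC")
  r <- rank(score)
  (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Pair-grouped repeated cross-validation of multilevel PLS-DA
#'
#' Folds are split by matched pair (both members held out together, so no
#' within-pair leakage); the within-pair decomposition is applied once (it
#' only mixes information inside a pair) and standardization parameters are
#' recomputed inside every training fold. AUC uses the held-out predicted
#' case score via the rank-sum formula; misclassification uses the max-score
#' rule. Reports mean and sd over repeats.
#'
#' @param X feature matrix (original scale, rownames = sample ids).
#' @param y named class labels (`"case"`/`"control"`) for rows of X.
#' @param pairs pair table.
#' @param n_components PLS components (default 2).
#' @param folds number of folds (default 5).
#' @param repeats number of CV repeats (default 50).
#' @param seed integer seed.
#' @return list with `auc_mean`, `auc_sd`, `mcr_mean`, `mcr_sd` and the
#'   per-repeat values.
#' @export
cross_validate_plsda <- function(X, y, pairs, n_components = 2, folds = 5,
                                 repeats = 50, seed = 1) {
  Xw <- multilevel_decompose(X, pairs)
  y <- y[rownames(X)]
  n_pairs <- nrow(pairs)
  if (folds > n_pairs) stop_mm("mm_domain_error", "more folds than pairs")
  pair_of <- setNames(rep(pairs$pair_id, 2), c(pairs$case_id, pairs$control_id))
  auc_r <- numeric(repeats); mcr_r <- numeric(repeats)
  set.seed(derive_seed(seed, "plsda_cv"))
  for (r in seq_len(repeats)) {
    fold_of_pair <- setNames(sample(rep_len(seq_len(folds), n_pairs)), pairs$pair_id)
    fold_of_sample <- fold_of_pair[pair_of[rownames(Xw)]]
    score <- setNames(numeric(nrow(Xw)), rownames(Xw))
    cls <- setNames(character(nrow(Xw)), rownames(Xw))
    for (f in seq_len(folds)) {
      test <- fold_of_sample == f
      fit <- plsda_fit(Xw[!test, , drop = FALSE], y[!test], n_components)
      pr <- predict(fit, Xw[test, , drop = FALSE])
      score[test] <- pr$class_scores[, "case"]
      cls[test] <- pr$class
    }
    auc_r[r] <- auc_rank(score, y == "case")
    mcr_r[r] <- mean(cls != y)
  }
  list(auc_mean = mean(auc_r), auc_sd = stats::sd(auc_r),
       mcr_mean = mean(mcr_r), mcr_sd = stats::sd(mcr_r),
       auc = auc_r, mcr = mcr_r)
}
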