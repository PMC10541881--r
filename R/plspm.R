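# Partial least squares path modeling: latent-variable structural models
# with reflective (mode A) indicator blocks, inner estimation by the path
# weighting scheme, direct/indirect effect decomposition, communality, R2,
# goodness of fit, and bootstrap percentile confidence intervals.
#
# No installed package provides PLS-PM, so the estimator is implemented
# here in full.

#' Specify a PLS path model
#'
#' A model is a set of named indicator blocks (each latent variable is a
#' reflective composite of its indicators) plus a lower-triangular inner
#' adjacency over the latents: `inner[i, j] = TRUE` means latent j (earlier
#' in the ordering) points to latent i. The inner graph must be acyclic,
#' which the lower-triangular form guarantees.
#'
#' @param blocks named list; each element is a character vector of indicator
#'   column names belonging to that latent. Single-indicator blocks (e.g. a
#'   binary mortality construct) are allowed.
#' @param inner square logical/0-1 matrix with `dimnames` equal to
#'   `names(blocks)`; strictly lower-triangular.
#' @return object of class `path_model_spec`.
#' @export
path_model_spec <- function(blocks, inner) {
  if (is.null(names(blocks)) || any(names(blocks) == "")) {
    stop_mm("mm_schema_error", "blocks must be a named list")
  }
  if (any(lengths(blocks) == 0)) stop_mm("mm_schema_error", "empty indicator block")
  inds <- unlist(blocks)
  if (anyDuplicated(inds)) {
    stop_mm("mm_schema_error", "indicator %s appears in more than one block",
            inds[duplicated(inds)][1])
  }
  inner <- as.matrix(inner)
  ln <- names(blocks)
  if (!identical(rownames(inner), ln) || !identical(colnames(inner), ln)) {
    stop_mm("mm_schema_error", "inner dimnames must equal names(blocks)")
  }
  inner <- inner != 0
  if (any(inner[upper.tri(inner, diag = TRUE)])) {
    stop_mm("mm_schema_error",
            "inner adjacency must be strictly lower-triangular (acyclic ordering)")
  }
  structure(list(blocks = blocks, inner = inner), class = "path_model_spec")
}

#' Fit a PLS path model (mode A, path weighting scheme)
#'
#' Iterative estimation on complete-case, standardized indicators:
#' outer weights start equal within each block; latent scores are the
#' standardized weighted indicator sums; the inner proxy of each latent
#' weights its predecessors by the coefficients of the regression of the
#' latent on them and its successors by correlations (path scheme); outer
#' weights are then updated as indicator-proxy correlations (mode A).
#' Iteration stops when the largest outer-weight change falls below `tol`.
#' Path coefficients are finally obtained by OLS of each endogenous latent
#' on its predecessors. Sign indeterminacy is resolved by forcing each
#' block's dominant loading positive.
#'
#' @param data numeric matrix or data.frame of indicators (complete cases,
#'   any scale; columns are standardized internally).
#' @param spec a [path_model_spec()].
#' @param tol convergence tolerance on outer weights (default 1e-6).
#' @param max_iter iteration cap (default 300).
#' @return object of class `path_model_fit`: `weights`, `loadings`,
#'   `scores`, `paths` (coefficient matrix, `paths[i, j]` = effect of j on
#'   i), `path_table`, `r2`, `communality`, `gof`, `effects` (from
#'   [effects_decomposition()]), `iterations`.
#' @export
fit_plspm <- function(data, spec, tol = 1e-6, max_iter = 300) {
  stopifnot(inherits(spec, "path_model_spec"))
  X <- as.matrix(data)
  inds <- unlist(spec$blocks)
  missing_cols <- setdiff(inds, colnames(X))
  if (length(missing_cols) > 0) {
    stop_mm("mm_schema_error", "data lacks indicator(s): %s",
            paste(missing_cols, collapse = ", "))
  }
  X <- X[, inds, drop = FALSE]
  if (anyNA(X)) stop_mm("mm_domain_error", "complete cases required; remove missing rows")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop_mm("mm_domain_error", "constant indicator(s): %s",
            paste(colnames(X)[sds == 0], collapse = ", "))
  }
  X <- scale(X)
  n <- nrow(X)
  ln <- names(spec$blocks)
  L <- length(ln)
  inner <- spec$inner
  adjacent <- inner | t(inner)

  # population-style standardization for internal consistency
  std <- function(v) (v - mean(v)) / stats::sd(v)

  w <- lapply(spec$blocks, function(b) rep(1 / sqrt(length(b)), length(b)))
  scores <- sapply(seq_len(L), function(k) std(X[, spec$blocks[[k]], drop = FALSE] %*% w[[k]]))
  colnames(scores) <- ln
  iterations <- 0
  repeat {
    iterations <- iterations + 1
    # inner proxies, path scheme
    Z <- matrix(0, n, L, dimnames = list(NULL, ln))
    for (k in seq_len(L)) {
      e <- numeric(L)
      preds <- which(inner[k, ])
      succs <- which(inner[, k])
      if (length(preds) > 0) {
        Yp <- scores[, preds, drop = FALSE]
        e[preds] <- solve(crossprod(Yp), crossprod(Yp, scores[, k]))
      }
      if (length(succs) > 0) {
        e[succs] <- stats::cor(scores[, succs, drop = FALSE], scores[, k])
      }
      if (!any(adjacent[k, ])) {
        stop_mm("mm_schema_error", "latent %s is isolated in the inner model", ln[k])
      }
      Z[, k] <- std(scores %*% e)
    }
    # outer weights, mode A
    max_delta <- 0
    for (k in seq_len(L)) {
      wk <- as.numeric(stats::cor(X[, spec$blocks[[k]], drop = FALSE], Z[, k]))
      sk <- X[, spec$blocks[[k]], drop = FALSE] %*% wk
      if (stats::sd(sk) == 0) {
        stop_mm("mm_domain_error", "degenerate block %s: zero-variance score", ln[k])
      }
      # normalize so comparisons across iterations are meaningful
      wk <- wk / sqrt(sum(wk^2))
      max_delta <- max(max_delta, max(abs(wk - w[[k]])))
      w[[k]] <- wk
      scores[, k] <- std(sk)
    }
    if (max_delta < tol) break
    if (iterations >= max_iter) {
      stop_mm("mm_convergence_error",
              "PLS-PM did not converge in %d iterations (last max weight change %.2e)",
              max_iter, max_delta)
    }
  }

  # sign alignment: dominant loading positive per block
  for (k in seq_len(L)) {
    lo <- as.numeric(stats::cor(X[, spec$blocks[[k]], drop = FALSE], scores[, k]))
    if (lo[which.max(abs(lo))] < 0) {
      scores[, k] <- -scores[, k]
      w[[k]] <- -w[[k]]
    }
  }
  loadings <- lapply(seq_len(L), function(k) {
    setNames(as.numeric(stats::cor(X[, spec$blocks[[k]], drop = FALSE], scores[, k])),
             spec$blocks[[k]])
  })
  names(loadings) <- names(w) <- ln

  # inner path coefficients by OLS per endogenous latent
  paths <- matrix(0, L, L, dimnames = list(ln, ln))
  r2 <- setNames(rep(NA_real_, L), ln)
  rows <- list()
  for (k in seq_len(L)) {
    preds <- which(inner[k, ])
    if (length(preds) == 0) next
    Yp <- scores[, preds, drop = FALSE]
    G <- crossprod(Yp) / (n - 1)
    if (rcond(G) < 1e-12) {
      stop_mm("mm_domain_error", "singular inner regression for latent %s", ln[k])
    }
    beta <- solve(G, stats::cor(Yp, scores[, k]))
    paths[k, preds] <- beta
    fitted <- Yp %*% beta
    r2[k] <- stats::var(as.numeric(fitted)) / stats::var(scores[, k])
    for (idx in seq_along(preds)) {
      rows[[length(rows) + 1]] <- data.frame(
        from = ln[preds[idx]], to = ln[k], coefficient = beta[idx])
    }
  }
  path_table <- do.call(rbind, rows)

  communality <- sapply(loadings, function(lo) mean(lo^2))
  fit <- structure(list(weights = w, loadings = loadings, scores = scores,
                        paths = paths, path_table = path_table,
                        r2 = r2, communality = communality,
                        spec = spec, iterations = iterations, n = n),
                   class = "path_model_fit")
  fit$effects <- effects_decomposition(fit)
  fit$gof <- goodness_of_fit(fit)
  fit
}

#' @export
print.path_model_fit <- function(x, ...) {
  cat(sprintf("<path_model_fit> %d latents, n=%d, %d iterations, GoF=%.3f\n",
              length(x$spec$blocks), x$n, x$iterations, x$gof))
  print(x$path_table)
  invisible(x)
}

#' Direct, indirect and total effects between latent variables
#'
#' Direct effect = the path coefficient (0 when no edge); indirect effect =
#' the sum over all directed paths of length two or more of the product of
#' edge coefficients; total = direct + indirect. Computed by the nilpotent
#' matrix power series `sum_k B^k`, which for an acyclic inner graph equals
#' brute-force path enumeration.
#'
#' @param fit a `path_model_fit`, or a bare coefficient matrix `B` with
#'   `B[i, j]` the direct effect of j on i (strictly lower-triangular).
#' @return data.frame with from, to, direct, indirect, total for every
#'   ordered latent pair connected by at least one path.
#' @export
effects_decomposition <- function(fit) {
  B <- if (inherits(fit, "path_model_fit")) fit$paths else as.matrix(fit)
  L <- nrow(B)
  if (any(B[upper.tri(B, diag = TRUE)] != 0)) {
    stop_mm("mm_schema_error", "coefficient matrix must be strictly lower-triangular (acyclic)")
  }
  total <- matrix(0, L, L, dimnames = dimnames(B))
  Bk <- B
  for (k in seq_len(L - 1)) {
    total <- total + Bk
    Bk <- Bk %*% B
  }
  indirect <- total - B
  ln <- rownames(B) %||% as.character(seq_len(L))
  rows <- list()
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (total[i, j] != 0 || B[i, j] != 0) {
        rows[[length(rows) + 1]] <- data.frame(
          from = ln[j], to = ln[i], direct = B[i, j],
          indirect = indirect[i, j], total = total[i, j])
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(from = character(), to = character(), direct = numeric(),
                      indirect = numeric(), total = numeric()))
  }
  do.call(rbind, rows)
}

#' Goodness of fit of a PLS path model
#'
#' `sqrt(mean communality x mean R2)`: the communality mean runs over
#' reflective blocks with at least two indicators (single-indicator blocks
#' have communality 1 by construction and carry no measurement information);
#' the R2 mean runs over endogenous latents.
#'
#' @param fit a `path_model_fit`.
#' @return scalar goodness of fit in \[0, 1\].
#' @export
goodness_of_fit <- function(fit) {
  multi <- lengths(fit$spec$blocks) > 1
  comm <- if (any(multi)) mean(fit$communality[multi]) else mean(fit$communality)
  r2 <- fit$r2[!is.na(fit$r2)]
  if (length(r2) == 0) stop_mm("mm_domain_error", "no endogenous latent in the model")
  sqrt(comm * mean(r2))
}

#' Bootstrap percentile confidence intervals for paths and effects
#'
#' Resamples subjects (rows) with replacement, refits the full model on each
#' resample, aligns each replicate's latent orientations to the original fit
#' (dominant-loading rule is applied within the refit, and any residually
#' flipped block is re-aligned by the sign of the loading inner product),
#' and reports percentile intervals for every path coefficient and for the
#' direct/indirect/total effects.
#'
#' @param data indicator matrix as in [fit_plspm()].
#' @param spec a [path_model_spec()].
#' @param B number of bootstrap resamples (default 1000, minimum 2).
#' @param seed integer seed.
#' @param conf_level interval mass (default 0.95).
#' @param tol,max_iter passed to [fit_plspm()].
#' @return list with `paths` (path_table plus ci_low/ci_high), `effects`
#'   (effects table plus per-column intervals), `n_failed` (non-convergent
#'   resamples, redrawn up to a cap) and the original `fit`.
#' @export
bootstrap_paths <- function(data, spec, B = 1000, seed = 1, conf_level = 0.95,
                            tol = 1e-6, max_iter = 300) {
  if (B < 2) stop_mm("mm_domain_error", "B must be at least 2")
  X <- as.matrix(data)
  fit0 <- fit_plspm(X, spec, tol = tol, max_iter = max_iter)
  ln <- names(spec$blocks)
  L <- length(ln)
  n <- nrow(X)
  path_idx <- which(spec$inner, arr.ind = TRUE)
  boot_paths <- matrix(NA_real_, B, nrow(path_idx))
  eff0 <- fit0$effects
  eff_key <- paste(eff0$from, eff0$to, sep = "->")
  boot_dir <- matrix(NA_real_, B, nrow(eff0))
  boot_ind <- matrix(NA_real_, B, nrow(eff0))
  boot_tot <- matrix(NA_real_, B, nrow(eff0))
  n_failed <- 0
  set.seed(derive_seed(seed, "plspm_boot"))
  for (b in seq_len(B)) {
    fb <- NULL
    for (attempt in 1:10) {
      rows <- sample.int(n, n, replace = TRUE)
      fb <- tryCatch(fit_plspm(X[rows, , drop = FALSE], spec,
                               tol = tol, max_iter = max_iter),
                     metabmort_error = function(e) NULL)
      if (!is.null(fb)) break
      n_failed <- n_failed + 1
    }
    if (is.null(fb)) next
    # align each replicate block orientation to the original fit
    flip <- sapply(seq_len(L), function(k) {
      sum(fit0$loadings[[k]] * fb$loadings[[k]]) < 0
    })
    Pb <- fb$paths
    for (k in which(flip)) {
      Pb[k, ] <- -Pb[k, ]
      Pb[, k] <- -Pb[, k]
    }
    boot_paths[b, ] <- Pb[path_idx]
    effb <- effects_decomposition(Pb)
    kb <- paste(effb$from, effb$to, sep = "->")
    m <- match(eff_key, kb)
    boot_dir[b, ] <- effb$direct[m]
    boot_ind[b, ] <- effb$indirect[m]
    boot_tot[b, ] <- effb$total[m]
  }
  if (n_failed > 0.05 * B) {
    warning(sprintf("%d non-convergent bootstrap resamples were redrawn", n_failed))
  }
  lo <- (1 - conf_level) / 2
  qs <- function(m) t(apply(m, 2, stats::quantile, probs = c(lo, 1 - lo), na.rm = TRUE))
  pq <- qs(boot_paths)
  paths <- data.frame(from = ln[path_idx[, 2]], to = ln[path_idx[, 1]],
                      coefficient = fit0$paths[path_idx],
                      ci_low = pq[, 1], ci_high = pq[, 2])
  dq <- qs(boot_dir); iq <- qs(boot_ind); tq <- qs(boot_tot)
  effects <- cbind(eff0,
                   direct_ci_low = dq[, 1], direct_ci_high = dq[, 2],
                   indirect_ci_low = iq[, 1], indirect_ci_high = iq[, 2],
                   total_ci_low = tq[, 1], total_ci_high = tq[, 2])
  list(paths = paths, effects = effects, n_failed = n_failed, fit = fit0)
}

#' Default path model for the malnutrition mortality study
#'
#' Four reflective latents plus a single-indicator mortality construct:
#' intestinal inflammation (calprotectin, MPO) -> luminal metabolism
#' (differential fecal metabolites, negative path) and -> circulating
#' microbial products (serum propionate, butyrate, isobutyrate, positive)
#' -> systemic inflammation (IL7, IL8, IL15, TNFa, GCSF, MCP1, positive)
#' -> mortality (positive). Direct edges from every latent to mortality are
#' included so the indirect/total decomposition is estimable.
#'
#' @param metabolites character vector of differential fecal metabolite
#'   column names forming the luminal metabolism block.
#' @param inflammation,microbial,systemic,mortality indicator column names
#'   of the remaining blocks.
#' @return a [path_model_spec()].
#' @export
default_path_spec <- function(metabolites,
                              inflammation = c("calprotectin", "mpo"),
                              microbial = c("serum_propionate", "serum_butyrate",
                                            "serum_isobutyrate"),
                              systemic = c("IL7", "IL8", "IL15", "TNFa",
                                           "GCSF", "MCP1"),
                              mortality = "mortality") {
  blocks <- list(IntestinalInflammation = inflammation,
                 LuminalMetabolism = metabolites,
                 CircMicrobialProducts = microbial,
                 SystemicInflammation = systemic,
                 Mortality = mortality)
  ln <- names(blocks)
  inner <- matrix(FALSE, 5, 5, dimnames = list(ln, ln))
  inner["LuminalMetabolism", "IntestinalInflammation"] <- TRUE
  inner["CircMicrobialProducts", "IntestinalInflammation"] <- TRUE
  inner["SystemicInflammation", "CircMicrobialProducts"] <- TRUE
  inner["Mortality", c("IntestinalInflammation", "LuminalMetabolism",
                       "CircMicrobialProducts", "SystemicInflammation")] <- TRUE
  path_model_spec(blocks, inner)
}
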