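enet_objective <- function(X, y, beta, icpt, alpha, lambda) {
  eta <- icpt + X %*% beta
  -mean(y * eta - log(1 + exp(eta))) +
    lambda * (alpha * sum(abs(beta)) + (1 - alpha) / 2 * sum(beta^2))
}

make_xy <- function(n, p, beta = NULL, seed = 1) {
  set.seed(seed)
  X <- scale(matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("v", 1:p))))
  if (is.null(beta)) beta <- rep(0, p)
  y <- rbinom(n, 1, plogis(X %*% beta))
  list(X = X, y = y)
}

test_that("zero penalty reproduces unpenalized maximum likelihood", {
  d <- make_xy(200, 4, c(1, -0.5, 0, 0), seed = 2)
  fit <- fit_enet_logistic(d$X, d$y, alpha = 0.5, lambda = 0, thresh = 1e-12)
  ml <- glm(d$y ~ d$X, family = binomial())
  expect_equal(unname(fit$beta[, 1]), unname(coef(ml)[-1]), tolerance = 1e-5)
})

test_that("penalties above lambda_max zero out every slope", {
  d <- make_xy(100, 6, c(1, rep(0, 5)), seed = 3)
  lambda_max <- max(abs(crossprod(d$X, d$y - mean(d$y)))) / (length(d$y) * 0.5)
  fit <- fit_enet_logistic(d$X, d$y, alpha = 0.5, lambda = lambda_max * 1.05)
  expect_true(all(fit$beta[, 1] == 0))
})

test_that("solutions satisfy the KKT conditions and beat perturbations", {
  set.seed(19)
  for (i in 1:5) {
    d <- make_xy(40, 6, rnorm(6, 0, 0.8), seed = 100 + i)
    lam <- 0.05
    fit <- fit_enet_logistic(d$X, d$y, alpha = 0.5, lambda = lam, thresh = 1e-13)
    beta <- fit$beta[, 1]; icpt <- fit$intercept[1]
    expect_lt(enet_kkt_violation(d$X, d$y, beta, icpt, 0.5, lam), 1e-6)
    f0 <- enet_objective(d$X, d$y, beta, icpt, 0.5, lam)
    worse <- replicate(200, {
      enet_objective(d$X, d$y, beta + rnorm(6, 0, 0.05), icpt, 0.5, lam)
    })
    expect_true(all(worse >= f0 - 1e-10))
  }
})

test_that("cross-validation is seeded, stratified and sane on pure noise", {
  d <- make_xy(80, 10, seed = 7)
  cv1 <- cv_select_lambda(d$X, d$y, seed = 5)
  cv2 <- cv_select_lambda(d$X, d$y, seed = 5)
  expect_identical(cv1$lambda_min, cv2$lambda_min)
  # 1-SE rule on pure noise keeps (almost) nothing
  fit <- fit_enet_logistic(d$X, d$y, lambda = cv1$lambda_1se)
  expect_lte(sum(fit$beta[, 1] != 0), 2)
})

test_that("fits are invariant to duplicating the data set", {
  d <- make_xy(60, 5, c(1, -1, 0, 0, 0), seed = 11)
  lam <- 0.03
  f1 <- fit_enet_logistic(d$X, d$y, lambda = lam, thresh = 1e-12)
  f2 <- fit_enet_logistic(rbind(d$X, d$X), c(d$y, d$y), lambda = lam,
                          thresh = 1e-12)
  expect_equal(unname(f1$beta[, 1]), unname(f2$beta[, 1]), tolerance = 1e-6)
})

test_that("a strong predictor enters the path first", {
  d <- make_xy(150, 8, c(2, rep(0, 7)), seed = 13)
  path <- glmnet::glmnet(d$X, d$y, family = "binomial", alpha = 0.5,
                         standardize = FALSE)
  first <- which(rowSums(as.matrix(path$beta) != 0) ==
                   max(rowSums(as.matrix(path$beta) != 0)))[1]
  expect_equal(unname(first), 1)
})

test_that("bootstrap stability selection is reproducible and calibrated", {
  # one strong analyte among noise, matched-pair design
  set.seed(29)
  n_pairs <- 68
  ids <- c(sprintf("c%02d", 1:n_pairs), sprintf("k%02d", 1:n_pairs))
  X <- matrix(rnorm(2 * n_pairs * 8), 2 * n_pairs, 8,
              dimnames = list(ids, paste0("v", 1:8)))
  y <- rep(c(1L, 0L), each = n_pairs)
  X[, 1] <- X[, 1] + y * 1.0
  X <- scale(X)
  pairs <- make_pairs(sprintf("c%02d", 1:n_pairs), sprintf("k%02d", 1:n_pairs))

  s1 <- bootstrap_stability(X, y, pairs, B = 100, seed = 3, retune = FALSE)
  s2 <- bootstrap_stability(X, y, pairs, B = 100, seed = 3, retune = FALSE)
  expect_identical(s1, s2)
  expect_true(s1$influential[1])                   # the true signal
  expect_lte(sum(s1$influential[-1]), 2)           # noise mostly excluded
  expect_true(all(s1$coef_q10 <= s1$coef_q90))
  # selection frequency column consistent with its own flag
  expect_equal(s1$influential_freq, s1$selection_freq > 0.8)
})

test_that("re-tuned and fixed-lambda bootstraps agree on a clear signal", {
  set.seed(33)
  n <- 60
  X <- scale(matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("v", 1:5))))
  y <- rbinom(n, 1, plogis(2 * X[, 2]))
  sA <- bootstrap_stability(X, y, B = 60, seed = 2, retune = TRUE)
  sB <- bootstrap_stability(X, y, B = 60, seed = 2, retune = FALSE)
  expect_true(sA$influential[2] && sB$influential[2])
})

test_that("feature union keeps provenance", {
  u <- c("alanine", "glycine")
  m <- c("alanine", "xanthine", "butyrate")
  res <- differential_feature_union(u, m)
  expect_equal(nrow(res), 4)
  expect_equal(res$source[res$analyte_id == "alanine"], "both")
  expect_equal(res$source[res$analyte_id == "glycine"], "univariate")
  expect_equal(res$source[res$analyte_id == "xanthine"], "multivariable")
  # idempotent on identical sets, additive on disjoint ones
  expect_equal(nrow(differential_feature_union(u, u)), 2)
  expect_equal(nrow(differential_feature_union(c("a", "b"), c("c", "d", "e"))), 5)
})
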