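# conditional log-likelihood for 1:1 pairs, used as a direct oracle
cond_loglik <- function(beta, d) sum(beta * d - log(1 + exp(beta * d)))

test_that("conditional logit equals direct likelihood maximization", {
  subj_vals <- function(d) {
    # build per-subject values realizing the given pair differences
    n <- length(d)
    v <- c(d, rep(0, n))
    names(v) <- c(sprintf("c%02d", 1:n), sprintf("k%02d", 1:n))
    v
  }
  prs <- function(n) make_pairs(sprintf("c%02d", 1:n), sprintf("k%02d", 1:n))

  # symmetric differences give a zero estimate
  r0 <- conditional_logit_1to1(subj_vals(c(1, -1)), prs(2))
  expect_equal(r0$estimate, 0, tolerance = 1e-8)

  d6 <- c(2, 1.5, 0.5, -0.5, -1, 3)
  r <- conditional_logit_1to1(subj_vals(d6), prs(6))
  opt <- optimize(cond_loglik, c(-10, 10), d = d6, maximum = TRUE,
                  tol = 1e-10)$maximum
  expect_equal(r$estimate, opt, tolerance = 1e-6)

  set.seed(8)
  for (i in 1:10) {
    d <- rnorm(10)
    r <- conditional_logit_1to1(subj_vals(d), prs(10))
    opt <- optimize(cond_loglik, c(-20, 20), d = d, maximum = TRUE,
                    tol = 1e-10)$maximum
    expect_equal(r$estimate, opt, tolerance = 1e-6)
  }
})

test_that("conditional logit agrees with the survival-package stratified fit", {
  skip_if_not_installed("survival")
  set.seed(12)
  n <- 40
  vals <- setNames(rnorm(2 * n, 5), c(sprintf("c%02d", 1:n), sprintf("k%02d", 1:n)))
  pairs <- make_pairs(sprintf("c%02d", 1:n), sprintf("k%02d", 1:n))
  r <- conditional_logit_1to1(vals, pairs)
  df <- data.frame(y = rep(c(1, 0), each = n),
                   x = c(vals[pairs$case_id], vals[pairs$control_id]),
                   stratum = rep(seq_len(n), 2))
  cl <- survival::coxph(survival::Surv(rep(1, 2 * n), y) ~ x +
                          survival::strata(stratum),
                        data = df, method = "exact")
  expect_equal(r$estimate, unname(coef(cl)), tolerance = 1e-6)
  expect_equal(r$se, sqrt(unname(vcov(cl)[1, 1])), tolerance = 1e-6)
})

test_that("conditional logit is invariant to per-pair constant shifts", {
  set.seed(9)
  n <- 20
  vals <- setNames(rnorm(2 * n), c(sprintf("c%02d", 1:n), sprintf("k%02d", 1:n)))
  pairs <- make_pairs(sprintf("c%02d", 1:n), sprintf("k%02d", 1:n))
  r1 <- conditional_logit_1to1(vals, pairs)
  shift <- rnorm(n, sd = 10)
  vals2 <- vals
  vals2[pairs$case_id] <- vals2[pairs$case_id] + shift
  vals2[pairs$control_id] <- vals2[pairs$control_id] + shift
  r2 <- conditional_logit_1to1(vals2, pairs)
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-9)
})

test_that("degenerate difference patterns raise classed errors", {
  pairs <- make_pairs(c("c1", "c2"), c("k1", "k2"))
  same_sign <- setNames(c(2, 1, 0, 0), c("c1", "c2", "k1", "k2"))
  expect_error(conditional_logit_1to1(same_sign, pairs),
               class = "mm_separation_error")
  zeroes <- setNames(c(1, 1, 1, 1), c("c1", "c2", "k1", "k2"))
  expect_error(conditional_logit_1to1(zeroes, pairs), class = "mm_domain_error")
})

test_that("matched estimator is consistent with near-nominal coverage", {
  set.seed(77)
  beta <- -0.7; n <- 68; reps <- 300
  est <- numeric(reps); cover <- logical(reps)
  for (r in seq_len(reps)) {
    d <- rnorm(n, 0, 1)
    # pair outcome: which member is the case given the difference
    case_first <- rbinom(n, 1, plogis(beta * d)) == 1
    d_obs <- ifelse(case_first, d, -d)
    vals <- setNames(c(d_obs, rep(0, n)),
                     c(sprintf("c%02d", 1:n), sprintf("k%02d", 1:n)))
    fit <- conditional_logit_1to1(vals, make_pairs(sprintf("c%02d", 1:n),
                                                   sprintf("k%02d", 1:n)))
    est[r] <- fit$estimate
    cover[r] <- fit$estimate - 1.96 * fit$se <= beta &
      beta <= fit$estimate + 1.96 * fit$se
  }
  expect_equal(mean(est), beta, tolerance = 0.1)
  expect_gt(mean(cover), 0.92)
  expect_lt(mean(cover), 0.99)
})

test_that("BH adjustment matches the step-up definition exactly", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
  p2 <- runif(10)
  expect_true(all(bh_fdr(p2) >= p2))
  expect_true(all(bh_fdr(p2) <= 1))
  expect_error(bh_fdr(c(0.5, 1.2)), class = "mm_domain_error")
})

test_that("2x2 odds ratios follow the Woolf construction", {
  sym <- odds_ratio_2x2(7, 7, 7, 7)
  expect_equal(sym$or_, 1)
  r <- odds_ratio_2x2(20, 10, 8, 16)
  expect_equal(r$or_, (20 * 16) / (10 * 8))
  expect_equal(r$ci_low,
               exp(log(r$or_) - qnorm(0.975) * sqrt(1 / 20 + 1 / 10 + 1 / 8 + 1 / 16)))
  z <- odds_ratio_2x2(5, 0, 3, 4)
  expect_true(z$corrected)
  expect_error(odds_ratio_2x2(5, 0, 3, 4, strict = TRUE), class = "mm_domain_error")
  expect_error(odds_ratio_2x2(-1, 2, 3, 4), class = "mm_domain_error")
})

test_that("IQR-scaled odds ratios rescale the per-unit estimate", {
  expect_equal(iqr_scaled_or(0, 1, 10)$or_iqr, 1)
  expect_equal(iqr_scaled_or(log(0.5), 1, 10, log10_scale = FALSE)$or_iqr,
               0.5^9)
  # arithmetic oracle on the log10 scale
  beta <- -1.2; q <- c(7.5, 23)
  expect_equal(iqr_scaled_or(beta, q[1], q[2])$or_iqr,
               exp(beta * (log10(q[2]) - log10(q[1]))))
  expect_error(iqr_scaled_or(1, 5, 5), class = "mm_domain_error")
})

test_that("adjusted logistic collapses to the univariate fit when covariates are constant", {
  set.seed(14)
  n <- 120
  df <- data.frame(died = rbinom(n, 1, 0.4), marker = rnorm(n, 500, 100),
                   age_months = 12, muac_cm = 10.5, hiv = "negative",
                   stringsAsFactors = FALSE)
  adj <- adjusted_logistic(df)
  uni <- glm(died ~ marker, data = df, family = binomial())
  expect_equal(adj$marker$estimate, unname(coef(uni)["marker"]), tolerance = 1e-8)
})

test_that("interaction Wald test holds its nominal size", {
  set.seed(23)
  reps <- 300; hits <- 0
  for (r in seq_len(reps)) {
    n <- 140
    df <- data.frame(marker = rnorm(n), edema = runif(n) < 0.3,
                     age_months = runif(n, 6, 48), muac_cm = runif(n, 8, 13),
                     hiv = sample(c("negative", "positive"), n, TRUE, c(0.8, 0.2)),
                     stringsAsFactors = FALSE)
    df$died <- rbinom(n, 1, plogis(-0.5 + 0.3 * df$marker))  # no interaction
    fit <- adjusted_logistic(df, edema_interaction = TRUE)
    hits <- hits + unname(fit$interaction_p < 0.05)
  }
  expect_lt(abs(hits / reps - 0.05), 0.035)
})

test_that("an edema-restricted marker effect yields the stratified pattern", {
  cfg <- sim_config(seed = 41, ifabp_edema_effect = 0.25)
  st <- simulate_study(cfg)
  s <- st$cohort$subjects
  df <- data.frame(died = as.integer(s$group == "case"),
                   marker = log10(st$markers$values[s$subject_id, "ifabp"]),
                   age_months = s$age_months, muac_cm = s$muac_cm,
                   hiv = s$hiv, edema = s$edema, stringsAsFactors = FALSE)
  fit <- adjusted_logistic(df, edema_interaction = TRUE)
  strat <- fit$stratified
  expect_gt(strat$or_[strat$stratum == "non-edema"],
            strat$or_[strat$stratum == "edema"])
  expect_gt(strat$or_[strat$stratum == "non-edema"], 1)
})

test_that("pairwise correlations give exact values, symmetry and honest NAs", {
  X <- cbind(x = c(1, 2, 3, 4), y = c(2, 4, 6, 8), z = c(1, -1, 2, 0),
             const = c(5, 5, 5, 5))
  res <- pairwise_pearson_fdr(X)
  expect_equal(res$r["x", "y"], 1)
  expect_equal(res$r, t(res$r))
  expect_equal(unname(diag(res$r)), rep(1, 4))
  expect_true(is.na(res$r["x", "const"]))
  expect_false(any(res$significant["const", ]))
})

test_that("null correlations are FDR-controlled", {
  set.seed(61)
  reps <- 200; any_sig <- 0; rbar <- 0
  for (r in seq_len(reps)) {
    X <- matrix(rnorm(100 * 4), 100, 4, dimnames = list(NULL, letters[1:4]))
    res <- pairwise_pearson_fdr(X)
    any_sig <- any_sig + any(res$significant[upper.tri(res$significant)])
    rbar <- rbar + mean(abs(res$r[upper.tri(res$r)]))
  }
  expect_lt(any_sig / reps, 0.12)   # BH familywise rate under the global null
  expect_lt(rbar / reps, 0.15)
})
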