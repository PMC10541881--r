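two_latent_spec <- function() {
  path_model_spec(list(A = "x1", B = "y1"),
                  matrix(c(FALSE, FALSE, TRUE, FALSE), 2, 2, byrow = TRUE,
                         dimnames = list(c("A", "B"), c("A", "B"))))
}

test_that("model specification validates block and inner structure", {
  expect_error(path_model_spec(list(A = "x", B = "x"),
                               matrix(FALSE, 2, 2,
                                      dimnames = list(c("A", "B"), c("A", "B")))),
               class = "mm_schema_error")
  bad_inner <- matrix(TRUE, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(path_model_spec(list(A = "x", B = "y"), bad_inner),
               class = "mm_schema_error")
})

test_that("single-indicator two-latent model reduces to the Pearson correlation", {
  set.seed(3)
  x <- rnorm(100)
  y <- 0.6 * x + rnorm(100, 0, 0.8)
  dat <- cbind(x1 = x, y1 = y)
  fit <- fit_plspm(dat, two_latent_spec())
  expect_equal(fit$path_table$coefficient, cor(x, y), tolerance = 1e-8)
  expect_equal(unname(fit$r2["B"]), cor(x, y)^2, tolerance = 1e-8)
})

test_that("single-indicator chains collapse to standardized OLS path analysis", {
  set.seed(5)
  n <- 300
  a <- rnorm(n)
  b <- 0.5 * a + rnorm(n, 0, 0.8)
  c_ <- 0.4 * b - 0.3 * a + rnorm(n, 0, 0.7)
  dat <- cbind(xa = a, xb = b, xc = c_)
  ln <- c("A", "B", "C")
  inner <- matrix(FALSE, 3, 3, dimnames = list(ln, ln))
  inner["B", "A"] <- TRUE
  inner["C", c("A", "B")] <- TRUE
  spec <- path_model_spec(list(A = "xa", B = "xb", C = "xc"), inner)
  fit <- fit_plspm(dat, spec)
  zs <- scale(dat)
  ols_b <- coef(lm(zs[, "xb"] ~ zs[, "xa"]))[2]
  ols_c <- coef(lm(zs[, "xc"] ~ zs[, "xa"] + zs[, "xb"]))[-1]
  expect_equal(fit$paths["B", "A"], unname(ols_b), tolerance = 1e-6)
  expect_equal(unname(fit$paths["C", c("A", "B")]), unname(ols_c),
               tolerance = 1e-6)
})

test_that("duplicated indicators share loadings and reproduce the block score", {
  set.seed(7)
  x <- rnorm(150)
  y <- 0.5 * x + rnorm(150, 0, 0.9)
  dat1 <- cbind(x1 = x, y1 = y)
  dat3 <- cbind(x1 = x, x2 = x, x3 = x, y1 = y)
  spec3 <- path_model_spec(list(A = c("x1", "x2", "x3"), B = "y1"),
                           matrix(c(FALSE, FALSE, TRUE, FALSE), 2, 2,
                                  byrow = TRUE,
                                  dimnames = list(c("A", "B"), c("A", "B"))))
  f1 <- fit_plspm(dat1, two_latent_spec())
  f3 <- fit_plspm(dat3, spec3)
  expect_equal(unname(f3$loadings$A), rep(1, 3), tolerance = 1e-8)
  expect_equal(f3$path_table$coefficient, f1$path_table$coefficient,
               tolerance = 1e-8)
})

test_that("latent scores are invariant to affine indicator rescaling", {
  sim <- simulate_path_data(300, seed = 9)
  f1 <- fit_plspm(sim$data, sim$spec)
  dat2 <- sim$data
  dat2[, "LM_x01"] <- 100 + 7 * dat2[, "LM_x01"]
  f2 <- fit_plspm(dat2, sim$spec)
  for (k in colnames(f1$scores)) {
    expect_gt(abs(cor(f1$scores[, k], f2$scores[, k])), 1 - 1e-8)
  }
})

test_that("a known latent structure is recovered at large n", {
  sim <- simulate_path_data(2000, seed = 13)
  fit <- fit_plspm(sim$data, sim$spec)
  truth <- c(-0.4, 0.5, 0.5, 0.3)
  est <- fit$path_table$coefficient
  expect_equal(sign(est), sign(truth))
  expect_true(all(abs(est - truth) < 0.12))
  # goodness of fit rises with loading strength
  lo <- fit_plspm(simulate_path_data(2000, loading = 0.5, seed = 13)$data, sim$spec)
  expect_gt(fit$gof, lo$gof)
})

test_that("effect decomposition matches brute-force path enumeration", {
  # worked chain: A->B 0.5, B->C 0.4
  B <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  B["B", "A"] <- 0.5; B["C", "B"] <- 0.4
  eff <- effects_decomposition(B)
  ac <- eff[eff$from == "A" & eff$to == "C", ]
  expect_equal(ac$direct, 0)
  expect_equal(ac$indirect, 0.2)
  expect_equal(ac$total, 0.2)
  # no multi-edge path: indirect zero
  ab <- eff[eff$from == "A" & eff$to == "B", ]
  expect_equal(ab$indirect, 0)
  # random DAGs vs DFS oracle
  set.seed(17)
  for (i in 1:30) {
    L <- sample(3:6, 1)
    M <- matrix(0, L, L)
    M[lower.tri(M)] <- rbinom(L * (L - 1) / 2, 1, 0.5) * round(runif(L * (L - 1) / 2, -1, 1), 2)
    dimnames(M) <- list(LETTERS[1:L], LETTERS[1:L])
    eff <- effects_decomposition(M)
    for (r in seq_len(nrow(eff))) {
      i_ <- match(eff$to[r], LETTERS[1:L]); j_ <- match(eff$from[r], LETTERS[1:L])
      expect_equal(eff$indirect[r], indirect_oracle(M, j_, i_), tolerance = 1e-10)
      expect_equal(eff$total[r], eff$direct[r] + eff$indirect[r], tolerance = 1e-12)
    }
  }
  # cycles rejected
  cyc <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(effects_decomposition(cyc), class = "mm_schema_error")
})

test_that("goodness of fit follows its defining arithmetic", {
  fake <- structure(list(
    communality = c(A = 0.49, B = 0.49, C = 1),
    r2 = c(A = NA, B = 0.25, C = 0.25),
    spec = list(blocks = list(A = c("a1", "a2"), B = c("b1", "b2"), C = "c1"))),
    class = "path_model_fit")
  expect_equal(goodness_of_fit(fake), sqrt(0.49 * 0.25))
})

test_that("bootstrap intervals are sign-aligned, additive and seeded", {
  sim <- simulate_path_data(250, seed = 21)
  bp1 <- bootstrap_paths(sim$data, sim$spec, B = 60, seed = 4)
  bp2 <- bootstrap_paths(sim$data, sim$spec, B = 60, seed = 4)
  expect_identical(bp1$paths, bp2$paths)
  expect_true(all(bp1$paths$ci_low <= bp1$paths$coefficient + 1e-8))
  expect_true(all(bp1$paths$ci_high >= bp1$paths$coefficient - 1e-8))
  eff <- bp1$effects
  expect_equal(eff$total, eff$direct + eff$indirect, tolerance = 1e-12)
})

test_that("null paths are covered near the nominal level", {
  set.seed(25)
  cover <- 0; reps <- 40
  for (r in seq_len(reps)) {
    sim <- simulate_path_data(150, paths = c(ii_lm = 0, ii_cmp = 0.5,
                                             cmp_si = 0.5, si_mort = 0.3),
                              block_sizes = c(II = 2, LM = 3, CMP = 3, SI = 3),
                              seed = 300 + r)
    bp <- bootstrap_paths(sim$data, sim$spec, B = 60, seed = r)
    row <- bp$paths[bp$paths$from == "II" & bp$paths$to == "LM", ]
    cover <- cover + (row$ci_low <= 0 && 0 <= row$ci_high)
  }
  expect_gte(cover / reps, 0.85)
})

test_that("degenerate indicators raise informative errors", {
  sim <- simulate_path_data(100, seed = 31)
  dat <- sim$data
  dat[, "II_x01"] <- 1
  expect_error(fit_plspm(dat, sim$spec), class = "mm_domain_error")
  expect_error(fit_plspm(sim$data[1:50, ],
                         path_model_spec(list(A = "II_x01", B = "II_x02"),
                                         matrix(FALSE, 2, 2,
                                                dimnames = list(c("A", "B"),
                                                                c("A", "B"))))),
               class = "mm_schema_error")  # isolated latents
})
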