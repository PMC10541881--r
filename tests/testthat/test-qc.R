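qc_fixture <- function() {
  # 10 study samples (5 case / 5 control) + 3 QC rows, 4 analytes:
  #  a: clean; b: CV 0.5; c: CV exactly 0.30; d: low detection
  ids <- sprintf("s%03d", 1:10)
  vals <- cbind(a = rep(10, 13), b = rep(10, 13), c = rep(10, 13), d = rep(10, 13))
  rownames(vals) <- c(ids, "qc1", "qc2", "qc3")
  vals[c("qc1", "qc2", "qc3"), "a"] <- c(10, 10, 10)
  vals[c("qc1", "qc2", "qc3"), "b"] <- c(1, 2, 3)      # CV = 0.5
  vals[c("qc1", "qc2", "qc3"), "c"] <- c(7, 10, 13)    # CV = 3/10 exactly
  vals[ids[1:7], "d"] <- NA                            # 3/10 detected overall
  m <- make_matrix(vals, is_qc = c(rep(FALSE, 10), rep(TRUE, 3)))
  grp <- setNames(rep(c("case", "control"), each = 5), ids)
  list(m = m, grp = grp)
}

test_that("QC CV filter computes sd/mean and applies the strict boundary", {
  fx <- qc_fixture()
  rep_ <- qc_cv_filter(fx$m)
  expect_equal(rep_$qc_cv, c(0, 0.5, 0.3, 0), tolerance = 1e-12)
  expect_equal(rep_$retained_qc, c(TRUE, FALSE, FALSE, TRUE))  # 0.30 removed
  one_qc <- make_matrix(matrix(1, 2, 1, dimnames = list(c("s1", "q1"), "a")),
                        is_qc = c(FALSE, TRUE))
  expect_error(qc_cv_filter(one_qc), class = "mm_domain_error")
})

test_that("detection filter uses the either-group inclusive 80% rule", {
  ids <- sprintf("s%03d", 1:20)
  vals <- cbind(x = rep(1, 20), y = rep(1, 20), z = rep(1, 20))
  rownames(vals) <- ids
  grp <- setNames(rep(c("case", "control"), each = 10), ids)
  vals[ids[1:3], "x"] <- NA               # 7/10 cases, 10/10 controls -> keep
  vals[c(ids[1:3], ids[11:13]), "y"] <- NA  # 7/10 and 7/10 -> drop
  vals[c(ids[1:2], ids[11:13]), "z"] <- NA  # 8/10 cases exactly -> keep
  m <- make_matrix(rbind(vals, qc1 = c(1, 1, 1), qc2 = c(1, 1, 1)),
                   is_qc = c(rep(FALSE, 20), TRUE, TRUE))
  rep_ <- detection_filter(m, grp)
  expect_equal(rep_$retained_detection, c(TRUE, FALSE, TRUE))
})

test_that("the two filters combine independently of order", {
  fx <- qc_fixture()
  full <- filter_report(fx$m, fx$grp)
  expect_equal(full$retained, full$retained_qc & full$retained_detection)
  expect_equal(full$analyte_id[full$retained], "a")
  expect_equal(full$reason[full$analyte_id == "b"], "qc_cv")
  expect_equal(full$reason[full$analyte_id == "d"], "detection")
})

test_that("half-minimum imputation alters only missing cells", {
  ids <- sprintf("s%03d", 1:5)
  vals <- cbind(a = c(4, 8, NA, 6, 12), b = c(1, 2, 3, 4, 5))
  rownames(vals) <- ids
  m <- make_matrix(rbind(vals, qc1 = c(1, 1), qc2 = c(1, 1)),
                   is_qc = c(rep(FALSE, 5), TRUE, TRUE))
  imp <- impute_missing(m)
  expect_equal(unname(imp$values["s003", "a"]), 2)     # half of min 4
  expect_equal(imp$values[ids, "b"], vals[, "b"])      # untouched column
  expect_equal(sum(attr(imp, "imputation_mask")), 1)
  # identity when nothing is missing
  expect_equal(impute_missing(imp)$values, imp$values)
})

test_that("imputed values under-estimate left-censored truth", {
  cfg <- sim_config(seed = 17, lod_quantile = 0.2, n_unstable = 0,
                    n_low_detection = 0)
  st <- simulate_study(cfg)
  m <- st$metabolome
  imp <- impute_missing(m)
  mask <- attr(imp, "imputation_mask")
  # every imputed half-minimum sits below the analyte's observed minimum,
  # hence below the censoring threshold
  for (j in which(colSums(mask) > 0)[1:5]) {
    lod <- min(m$values[!m$is_qc, j], na.rm = TRUE)
    expect_true(all(imp$values[mask[, j], j] < lod))
  }
})

test_that("log10 transform and z-scoring behave as documented", {
  ids <- sprintf("s%03d", 1:4)
  vals <- cbind(a = c(100, 10, 1000, 100), b = c(5, 5, 5, 5))
  rownames(vals) <- ids
  m <- make_matrix(vals)
  lv <- transform_standardize(m)
  expect_equal(unname(lv[1, "a"]), 2)
  # ranks preserved by monotone transform
  expect_equal(order(lv[, "a"]), order(vals[, "a"]))
  expect_warning(z <- transform_standardize(m, standardize = TRUE),
                 "zero-variance")
  expect_false("b" %in% colnames(z))
  expect_equal(mean(z[, "a"]), 0, tolerance = 1e-12)
  expect_equal(sd(z[, "a"]), 1, tolerance = 1e-12)

  vals2 <- vals; vals2[1, 1] <- 0
  expect_error(transform_standardize(make_matrix(vals2)), class = "mm_domain_error")
})

test_that("class summaries total raw concentrations and normalize per sample", {
  ids <- c("s001", "s002")
  vals <- cbind(a = c(3, 1), b = c(7, 1), c = c(10, 2))
  rownames(vals) <- ids
  cls <- c(a = "amino acid and derivative", b = "amino acid and derivative",
           c = "SCFA")
  m <- make_matrix(vals, classes = cls)
  cs <- class_summaries(m, group = setNames(c("case", "control"), ids))
  expect_equal(unname(cs$totals["s001", "amino acid and derivative"]), 10)
  expect_equal(unname(rowSums(cs$proportions)), c(1, 1))
  expect_equal(nrow(cs$group_summary), 4)
})

test_that("a depressed amino acid class shows up in case-group means", {
  hits <- 0
  for (seed in 1:10) {
    st <- simulate_study(sim_config(seed = 100 + seed))
    grp <- setNames(st$cohort$subjects$group, st$cohort$subjects$subject_id)
    imp <- impute_missing(st$metabolome)
    cs <- class_summaries(imp, group = grp)
    gs <- cs$group_summary
    aa <- gs[gs$class == "amino acid and derivative", ]
    hits <- hits + (aa$mean[aa$group == "case"] < aa$mean[aa$group == "control"])
  }
  expect_gte(hits, 9)
})
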