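# Small in-code fixtures used across the suite.

make_subjects <- function(n, group = rep(c("case", "control"), length.out = n),
                          seed = 1) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("s%03d", seq_len(n)),
    group = group,
    age_months = round(runif(n, 6, 48), 1),
    muac_cm = round(runif(n, 8, 13), 1),
    hiv = sample(c("negative", "positive", "unknown"), n, TRUE, c(0.7, 0.25, 0.05)),
    edema = runif(n) < 0.3,
    stringsAsFactors = FALSE
  )
}

make_pairs <- function(case_ids, control_ids) {
  data.frame(pair_id = sprintf("p%03d", seq_along(case_ids)),
             case_id = case_ids, control_id = control_ids,
             stringsAsFactors = FALSE)
}

# analyte matrix with ns study samples, nq QC rows
make_matrix <- function(values, classes = NULL, units = NULL, basis = "dry",
                        is_qc = NULL) {
  an <- colnames(values)
  if (is.null(classes)) classes <- setNames(rep("SCFA", length(an)), an)
  if (is.null(units)) units <- setNames(rep("umol/g dry", length(an)), an)
  analyte_matrix(values, units, classes, basis = basis, is_qc = is_qc)
}

# independent BH implementation straight from the step-up definition
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# brute-force sum over all simple directed paths of length >= 2 (DFS)
indirect_oracle <- function(B, from, to) {
  L <- nrow(B)
  total <- 0
  walk <- function(node, prod_, len) {
    if (node == to && len >= 2) {
      total <<- total + prod_
      return(invisible())
    }
    for (nxt in seq_len(L)) {
      if (B[nxt, node] != 0) walk(nxt, prod_ * B[nxt, node], len + 1)
    }
  }
  walk(from, 1, 0)
  total
}

# exhaustive concordant-pair AUC
auc_oracle <- function(score, is_case) {
  cs <- score[as.logical(is_case)]
  ct <- score[!as.logical(is_case)]
  conc <- 0
  for (a in cs) for (b in ct) conc <- conc + (a > b) + 0.5 * (a == b)
  conc / (length(cs) * length(ct))
}
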