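# Internal helpers shared across stages.

#' Round half away from zero at a fixed number of decimals
#'
#' Report tables print odds ratios at one decimal and proportions as whole
#' percentages using conventional half-up rounding (2.45 -> 2.5), not the
#' round-half-even rule of [base::round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(2.417, 1)  # 2.4
#' round_half_up(3.052, 1)  # 3.1
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Derive independent 32-bit sub-seeds from a master seed, one per logical
# block, so adding a block to the generator never perturbs another block's
# random stream.  Linear congruential step modulo the Mersenne prime 2^31-1.
derive_seed <- function(seed, block) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  h <- (abs(seed) %% 2147483646) + 1
  for (ch in utf8ToInt(as.character(block))) {
    h <- (h * 48271 + ch) %% 2147483647
  }
  as.integer(h)
}

# Stop with a classed condition so callers/tests can distinguish error kinds.
stop_mm <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "metabmort_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample sd / mean; the conventional QC coefficient of variation on the raw
# concentration scale.
coef_variation <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / mean(x)
}
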