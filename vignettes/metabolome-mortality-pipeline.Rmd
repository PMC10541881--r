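---
title: "Linking the fecal metabolome and enteropathy to mortality in severe malnutrition: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking the fecal metabolome and enteropathy to mortality in severe malnutrition: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabmort)
```

## The analysis problem

Children hospitalized with complicated severe malnutrition (CSM) die at high
rates despite standardized management. `metabmort` implements a matched
case-control analysis chain for studies that compare children who died
in hospital (cases, nonsurvivors) with children discharged alive (controls,
survivors) on their admission fecal metabolome and enteropathy markers
(fecal calprotectin, myeloperoxidase, alpha-1-antitrypsin; serum I-FABP),
and then place intestinal disturbances on a causal path toward mortality
together with systemic data.

The chain is: propensity-score 1:1 matching; quality filtering of a
targeted metabolite panel; detection-limit imputation and log10
transformation; matched univariate screening by conditional logistic
regression with Benjamini-Hochberg false discovery rate control; elastic-net
penalized logistic regression with bootstrap stability selection;
multilevel partial least squares discriminant analysis (PLS-DA) of the
differential features; FDR-screened Pearson correlation networks; and a
partial least squares path model (PLS-PM) with direct/indirect effect
decomposition. A seeded synthetic-cohort generator with known ground truth
backs every stage with a parameter-recovery test.

## Matching

Controls are matched to cases 1:1 on the propensity score for death,
estimated by maximum-likelihood logistic regression of the outcome on age
(months), MUAC (cm) and HIV status, with HIV kept as three strata
(negative, positive, unknown/refused). Matching is greedy nearest-neighbor
without replacement on the raw score distance, processing cases in
descending score order, with control-identifier ties broken lexically so a
rerun reproduces the same pairs. These are deliberate choices where the
design space is genuinely open: greedy matching is the simplest
reproducible scheme (optimal matching would be a natural extension), raw
score distance is used rather than the logit of the score, and no caliper
is applied by default (a caliper argument exists; a zero caliper with no
exact ties matches nothing, by construction). Balance can be audited with
`covariate_balance()`, which reports standardized mean differences before
and after matching.

## Quality filtering, imputation, transformation

A metabolite is retained when **both** hold:

* its coefficient of variation (sample sd / mean, raw concentration scale)
  over quality-control replicate injections is strictly below 0.30 — a CV
  of exactly 0.30 is removed;
* it is detected (non-missing) in at least 80% of samples in the case
  group *or* in the control group — exactly 80% in one group is retained.

The two filters commute, and `filter_report()` records the verdict and the
reason for every analyte. Missing values in retained analytes are treated
as left-censoring below the detection limit and imputed by half the
minimum observed value of that analyte (a conventional surrogate; the
imputation mask is kept for audit, observed values are never modified).
Concentrations are log10-transformed for modeling; multivariable stages
additionally z-score each analyte, with standardization parameters always
computed inside the training portion of any cross-validation fold.
Wet-weight and dry-weight bases are kept distinct: `wet_to_dry()` divides
by one minus the measured fecal water fraction, units travel as metadata,
and cutoff comparisons refuse to run on a mismatched basis rather than
silently converting.

## Matched univariate screen

For a 1:1 matched pair with case-minus-control difference $d_i$ on the
log10 scale, the conditional likelihood of the pair is
$e^{\beta d_i}/(1 + e^{\beta d_i})$; the product over pairs is maximized
by intercept-free logistic regression of a constant response on the
differences, which is how `conditional_logit_1to1()` computes the estimate
(the equivalence is tested against direct likelihood maximization and
against the stratified proportional-hazards formulation). The estimator is
invariant to adding any constant to both members of a pair. Inference is
by two-sided Wald tests; multiplicity is handled by Benjamini-Hochberg
adjustment; an all-one-sign difference pattern has an infinite conditional
MLE and is reported as a separation error rather than a number. Per-IQR
odds ratios (`iqr_scaled_or()`) re-express a per-unit log-odds as the
effect of moving from the 25th to the 75th percentile of the analyte.

Serum I-FABP is analyzed unpaired (in real studies several pairs have only
one member with serum available): unconditional logistic regression
adjusted for the matching covariates, optionally with an edema interaction
whose Wald p-value and implied stratum-specific odds ratios are reported.
Constant covariates are dropped from the adjustment rather than breaking
the model matrix.

## Elastic net and bootstrap stability selection

The multivariable screen minimizes
$-\tfrac1n \ell(\beta) + \lambda(\alpha\|\beta\|_1 +
\tfrac{1-\alpha}{2}\|\beta\|_2^2)$ on the standardized log10 matrix
(delegated to coordinate descent in glmnet; solutions are audited against
the subgradient KKT conditions). Choices where the protocol is open, all
exposed as arguments:

* mixing parameter $\alpha = 0.5$ (balanced elastic net) by default;
* $\lambda$ tuned by outcome-stratified 5-fold cross-validated deviance on
  a 100-point grid spanning four decades below $\lambda_{\max}$;
* $B = 1000$ bootstrap resamples by default, resampling **matched pairs
  jointly** to preserve the design (subject-level resampling available);
* $\lambda$ re-tuned inside every resample by default (avoids optimism;
  a fixed-lambda mode exists for speed);
* an analyte is *influential* when the central 80% percentile interval
  (10th-90th) of its bootstrap coefficients excludes zero; the alternative
  reading — selected in more than 80% of resamples — is computed alongside
  and can be made the deciding criterion.

The differential feature set is the union of univariate hits (raw
p < 0.05) and influential analytes, with per-feature provenance.

## Multilevel PLS-DA

Paired designs carry large between-pair variation that is irrelevant to
the case/control contrast. `multilevel_decompose()` removes it:
$X_w = X - X_{\text{pair means}} + \bar X$, an exact decomposition whose
within part has pair means equal to the grand mean. PLS-DA is a NIPALS
PLS2 regression of the one-hot class matrix on $X_w$ (2 components by
default, matching the common two-component score plot), with unit-norm
weights, orthogonal scores, and prediction by the maximum predicted class
score — ties go to the control class, a conservative convention.
Cross-validation is 5-fold with 50 repeats, splitting **by pair** so both
members are held out together; AUC is computed from held-out case scores
by the rank-sum (concordant-pair) formula and reported as mean ± sd over
repeats alongside the misclassification rate.

## PLS path modeling

The structural model has four reflective latents — intestinal inflammation
(calprotectin, MPO), luminal metabolism (the differential fecal
metabolites), circulating microbial products (serum propionate, butyrate,
isobutyrate), systemic inflammation (IL7, IL8, IL15, TNFa, GCSF, MCP1) —
plus mortality as a single-indicator construct, with the directed inner
graph: inflammation to luminal metabolism (expected negative), inflammation
to circulating microbial products (positive), microbial products to
systemic inflammation (positive), and each latent to mortality.
Indicators are log10-transformed, standardized, complete-case.

Estimation is the classical iterative composite scheme: mode A outer
weights (indicator-proxy correlations), path weighting scheme for the
inner proxies (predecessors weighted by regression coefficients,
successors by correlations), convergence when the largest outer-weight
change drops below 1e-6 (cap 300 iterations, both configurable), then OLS
path coefficients per endogenous latent. Centroid/factorial inner schemes
were considered; the path scheme is the methodology's common default and
is what we implement. Sign indeterminacy is fixed by forcing each block's
dominant loading positive, and bootstrap replicates are re-aligned to the
original orientation before interval computation.

Effects decompose as: direct = edge coefficient; indirect = sum over all
directed paths of length two or more of the products of edge coefficients
(computed by the nilpotent power series, verified against exhaustive path
enumeration); total = direct + indirect, an identity that holds for every
fitted and every bootstrapped model. The goodness of fit is
$\sqrt{\overline{\text{communality}} \times \overline{R^2}}$, where the
communality mean runs over blocks with at least two indicators
(single-indicator blocks have communality 1 by construction and would
only dilute the measure) and the $R^2$ mean over endogenous latents.
Intervals are percentile bootstrap over subject resamples — the simplest
defensible reading of a bootstrap-validated path model; BCa would be an
extension. Mortality enters as a standardized binary indicator; a logistic
outer model is out of scope.

A known attenuation is worth stating: composite scores are imperfect
proxies for the latents, so path estimates shrink by roughly the product
of the block score-latent correlations. With loadings of 0.8 this factor
is about 0.88 for a 2-indicator block and 0.92-0.98 for larger blocks;
recovery checks therefore compare the *estimate* to the truth within a
±0.1 band rather than expecting unbiasedness.

## The synthetic-cohort generator

`simulate_study()` emulates the study the package is designed for, and its
defaults are the study conditions, not tuning knobs:

* a survivor pool of 653 and an expected 68 cases (the mortality-logit
  intercept is calibrated so the expected case count matches; the draw is
  Bernoulli, so the realized count varies);
* 68 targeted metabolites in six classes with shares SCFA 0.30, carboxylic
  acids 0.26, carbohydrates 0.19, amino acids and derivatives 0.13,
  alcohols 0.09, other 0.03 (largest-remainder apportionment);
* a 15-metabolite true differential set concentrated in amino acids and
  carbohydrates, shifted by −0.3 log10 in cases. The scale is anchored to
  the one quantitative anchor available for group separation: a factor-two
  reduction in total amino acids (about 96 vs 192 µmol/g dry weight), which
  −0.3 log10 reproduces with class baselines near 21 µmol/g per amino
  acid;
* log10-normal concentration noise with sd 0.5 (fecal analytes are highly
  variable), left-censoring at a detection-limit quantile (default 5%;
  four designated low-detection analytes are censored at 50% so the
  detection filter removes exactly them);
* QC replicate rows whose *sample* CV is pinned exactly to the configured
  target (0.10 for stable analytes, 0.50 for three designated unstable
  ones) — pinning the sample rather than the population CV makes the QC
  filter's verdict a deterministic function of the configuration, so
  filter tests do not depend on the luck of an 8-replicate draw;
* fecal water content uniform on 0.60-0.85, the physiological range;
* a standardized latent chain: intestinal inflammation to luminal
  metabolism (−0.4), to circulating microbial products (+0.5), microbial
  products to systemic inflammation (+0.5), and a positive systemic
  inflammation effect on the mortality logit, with marker and systemic
  indicator loadings of 0.8. These magnitudes sit in the 0.2-0.5 band
  typical of standardized path coefficients in this literature;
* one independent random stream per logical block (covariates, latents,
  outcome, metabolome, QC, water, markers, systemic), each derived from
  the master seed, so extending one block never perturbs another.

`simulate_path_data()` is a leaner linear-Gaussian generator for
path-model recovery studies, with mortality as a continuous
single-indicator construct so all relationships stay linear.

What the generator does **not** emulate: real microbiome compositional
structure, correlated metabolite panels beyond the single latent factor,
batch or drift effects, informative missingness other than left-censoring,
longitudinal sampling, or raw NMR spectra. Passing recovery tests
therefore demonstrate that the estimators do what they claim under the
stated model — not that real fecal data satisfy that model.

## Numerical conventions and problem sizes

Report tables round half away from zero at the printed precision (odds
ratios one decimal, proportions whole percent), keeping full precision in
companion columns. Woolf (log-scale) intervals are used for 2x2 odds
ratios, with the Haldane-Anscombe 0.5 correction (flagged) on zero cells.
Exceedance against clinical cutoffs is strict: a value exactly at the
cutoff is not elevated. Missing values never enter proportion
denominators; missingness counts are reported alongside.

The bundled checks run at deliberately modest sizes chosen to make their
Monte-Carlo error small relative to the tolerance being asserted: null
error-control at 200 replicates of a 68-pair, 61-metabolite study;
stability-selection calibration at 25 replicates of 100 bootstrap
resamples with fixed-lambda refits; path-model recovery at 200 replicates
of n = 1000; interval coverage at 40 replicates of 60-resample bootstraps.
Defaults in the user-facing functions are larger (B = 1000) because a
single real analysis can afford them.

## Known limitations

Greedy matching is not optimal matching; exact conditional inference and
Firth correction for separated logits are not provided (separation is
reported, not silently penalized); the path model is composite-based
(PLS), not covariance-based SEM, and inherits the attenuation discussed
above; formative measurement blocks and higher-order constructs are out of
scope; and the generator's single-latent metabolite dependence is a
simplification of real metabolome covariance.
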