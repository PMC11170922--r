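---
title: "Methods: trans-ancestry PRS and ERS risk stratification on synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trans-ancestry PRS and ERS risk stratification on synthetic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(transprs)
```

This vignette documents the statistical models behind `transprs`, the
assumptions they make, the tunable parameters and why their defaults are
what they are, and the design choices taken where more than one reasonable
convention exists. Everything quantitative shown here is computed by the
code at build time or by the test suite; nothing is transcribed from
elsewhere.

## The generative model

All downstream machinery is exercised against a synthetic two-ancestry
scenario whose structure mirrors what a colorectal screening analysis
assumes about its data.

**Genotypes.** Effect-allele frequencies start from a shared base
distribution (uniform on (0.05, 0.95) by default) and diverge per ancestry
under the Balding–Nichols model: `p_anc ~ Beta(p(1-F)/F, (1-p)(1-F)/F)`,
so the expected frequency is preserved while `fst` controls divergence.
Defaults of `fst = 0.05` (target, East-Asian-like label) and `0.10`
(European-like label) produce the moderate cross-ancestry frequency
correlation typical of continental pairs. Haplotypes are drawn by
thresholding a latent Gaussian that follows an AR(1) process within each
LD block (`ld_rho = 0.8`, `block_size = 40` by default), independent
across blocks. This gives closed-form pairwise LD expectations (tested
against one-dimensional numeric integration of the bivariate normal),
monotone LD decay with distance — exactly what greedy clumping needs — and
nothing else: there is no recombination map, no inter-block LD, and no
imputation-quality structure.

**Outcomes.** Disease stage comes from a liability threshold model:
liability = Σ wᵢ·dosageᵢ + Σ vⱼ·flagⱼ + ε, ε ~ N(0, noise_sd²), with two
strictly increasing cutoffs separating normal, non-advanced adenoma (NAA)
and advanced neoplasm; advanced individuals are split 0.9/0.1 into
advanced adenoma vs carcinoma, echoing the roughly 9:1 ratio seen in
screening-detected advanced neoplasia. `liability_thresholds()` places the
cutoffs analytically (independent-variant approximation) so a scenario can
be specified by target stage proportions — defaults 15% NAA and 5–6%
advanced, i.e. a screening population, not a case-control set. The
liability formulation is a modelling stand-in: it reproduces the
qualitative stage gradient of a genetic score (normal < NAA < advanced)
and gives closed-form stage probabilities for testing, but it does not
model progression time or age-period-cohort structure.

**Lifestyle.** Five raw factors are generated so their binarized unhealthy
flags hit configured prevalences (defaults: smoking 0.30, alcohol 0.25,
low activity 0.60, poor diet 0.40, high BMI 0.45 — plausible for an
average-risk East Asian screening population). Liability consumes the
*binarized* flags, matching how the ERS consumes them, with default
log-ORs of 0.20–0.35 per flag. Missingness is missing-completely-at-random
(5% by default); stratified missingness is left to configuration.

**Summary statistics.** Per-variant estimates are drawn
`β̂ ~ N(β, se²)` with the standard case-control SE
`se = sqrt((1/n_cases + 1/n_controls)/(2p(1-p)))`, Wald P-values, and
binomially perturbed EAFs. Both ancestries share true effects by default,
so Cochran's Q is calibrated under homogeneity; heterogeneity can be
injected to exercise the filter.

**Follow-up.** Event times are exponential with rate
`baseline_hazard × HR(group)`, administratively censored at `max_years`
(defaults 0.004/person-year and 10 years, giving single-digit percent
cumulative incidence as in screening cohorts). Exponential hazards make
the expected event fraction `1 - exp(-h·t)` available in closed form for
testing.

## Meta-analysis

Studies are combined per variant by inverse-variance fixed effects
(weights `1/se²`), with Cochran's Q on K−1 degrees of freedom. Choices:

* **Genomic control is applied per study, before pooling**, and λ never
  deflates (λ ≤ 1 leaves a study untouched). Correcting each study first
  is the convention of the standard meta-analysis workflow and keeps the
  Q statistic honest when one study is inflated.
* **Harmonization** matches by variant id, flips sign and EAF when a
  study's allele pair is swapped relative to the reference study, drops
  incompatible pairs, and drops strand-ambiguous (A/T, C/G) variants whose
  EAF lies in [0.4, 0.6] in any study. The ambiguous-variant rule is the
  conservative convention: near 50% frequency the strand cannot be
  resolved from frequency alone.
* **Filtering** removes heterogeneity P < 0.001, variants absent from any
  required ancestry, and minor allele frequency below 0.1% (the per-study
  QC floor, exposed as `maf_cut`).

The implementation is tested against intercept-only weighted least squares
and against `metafor`'s fixed-effects fit to 10⁻⁸–10⁻¹⁰.

## PRS construction

Clumping is the standard greedy rule: visit variants at `pval ≤ p_cut` in
ascending P (ties broken by chromosome, position, id); reject a variant
within 250 kb (`|pos_a − pos_b| < 250,000`, same chromosome) of an
accepted variant when their r² exceeds `r2_cut`. LD is the squared Pearson
correlation of dosages in the target genotype panel itself — real
pipelines would plug in an external reference panel, and the LD source is
deliberately behind a single function (`ld_r2`) for that reason. Scoring
is Σ βᵢ·dosageᵢ with dosage reflection (`2 − d`) when the panel counts the
opposite allele and `2×EAF` mean imputation of missing dosages, the
behaviour of the common scoring tools. Z-standardization defaults to the
full scored sample; a reference subset can be supplied.

The (p_cut, r2_cut) cell is selected by repeated stratified k-fold
cross-validation of out-of-fold AUC. The full design is 400 repeats of
5 folds; the demo scenario and the tests run 20×5, which is enough to
rank grid cells at these effect sizes. The CV objective is the *crude*
out-of-fold AUC of the score — weights come from external summary
statistics, so no fold-level refitting is involved and the folds serve to
average over evaluation-sample variability. Ties prefer the smaller
`p_cut` (sparser score), then the larger `r2_cut`.

## ERS construction

A factor is healthy only as: never smoker; never drinker; physical
activity > 4 sessions/week; diet quality score ≥ 5 of 8; BMI < 24 kg/m²
(the East Asian overweight cutoff; the boundary value 24 itself is
unhealthy). Unhealthy is coded 1 so the fitted weights are positive risk
increments. Missing raw values are completed by predictive mean matching
within sex × 5-year age bands (5-year bands match the usual case-control
matching granularity), drawing from the `k = 5` nearest donors by
predicted mean and falling back to the whole cohort when a stratum is
empty. Weights are the flag coefficients of one maximum-likelihood
logistic model of advanced neoplasm on all flags jointly plus covariates —
an unconditional fit; conditional (matched-set) weight estimation is out
of scope here. The ERS is the weighted flag sum, z-standardized, with
20/60/20 (low/middle/top) categories cut at the 20th/80th percentiles.

## Evaluation layer

* **AUC** is the tie-aware (midrank) Mann–Whitney statistic; "adjusted
  AUC" is the same statistic applied to the linear predictor of the
  covariate-adjusted logistic model — one concrete choice among several
  definitions of covariate-adjusted discrimination.
* **Percentile cutoffs** (top-k, deciles, 20/60/20) are computed on the
  combined analysis sample; controls-only standardization is available by
  passing an explicit reference.
* **Screening metrics** come from the raw 2×2 table at the (1−k) quantile
  threshold; the OR of high-risk vs rest is covariate-adjusted. The
  counting identity sens·n_cases + (1−spec)·n_controls ≈ k·n is asserted
  in tests.
* **Additive interaction** dichotomizes both scores as top 20% vs rest,
  fits one logistic model with the three exposure-cell indicators, and
  computes RERI, AP and the synergy index S with delta-method CIs on the
  fitted log-OR covariance (the Hosmer–Lemeshow construction; S and the
  multiplicative ratio on the log scale). S is reported as missing with a
  warning when OR₁₀ + OR₀₁ ≤ 2, where its denominator changes sign.
* **Follow-up** uses Kaplan–Meier cumulative incidence, person-year rates
  per 100,000, and Cox models with Breslow ties and time origin at cohort
  entry, via the `survival` package.

## The Gaussian liability oracles

Under an equal-variance binormal model — score ~ N(0,1) in controls and
N(μ,1) in cases with μ = ln(OR per SD) — discrimination and screening
performance are fully determined:

* `binormal_auc_from_or(or)` returns Φ(ln(or)/√2).
* `gaussian_topk_oracle(or, n_cases, n_controls, k)` solves
  `(1−π)·Φc(t) + π·Φc(t−μ) = k` for the threshold t by bracketing root
  finding (tolerance 10⁻⁸) and derives sensitivity, specificity, PPV and
  NPV from the mixture and Bayes' rule with π = n_cases/(n_cases+n_controls).

These are the package's analytic cross-checks: they connect a reported
per-SD odds ratio and case mix to the crude AUC and top-k screening
metrics they imply, and they are themselves validated against ~10⁷-draw
Monte-Carlo simulations of the same mixture (agreement well within 0.005
per metric).

## Numerical choices and degenerate inputs

* Every generator is a pure function of (configuration, seed); seeds are
  saved/restored so library calls never perturb the caller's RNG stream,
  and pipeline stages derive sub-seeds from one master seed recorded in
  the output manifest.
* Zero-variance variants yield `r² = 0` with a warning (missing LD is
  treated as absence of LD, the permissive choice for clumping).
* A score that is constant (e.g. all weights zero) gets z-scores of 0;
  association estimators refuse constant scores instead.
* Logistic fits flag separation (|coef| > 10 or non-convergence) as errors
  naming the offending factor.
* Single-class cross-validation folds are skipped with a warning rather
  than poisoning the AUC average.
* Allele-frequency draws are clamped to [10⁻⁴, 1−10⁻⁴] so simulated SEs
  stay finite.

## What the tests do and do not show

The "population value" used in parameter-recovery tests for the per-SD OR
deserves a note: the liability model is probit, so no closed-form logistic
coefficient exists for it. Recovery is therefore tested against an
independent 100,000-sample replicate of the same generative process —
i.e. the tests show estimator stability at realistic n against a
brute-force estimate of the population quantity, not agreement with an
algebraic constant.

Problem sizes were chosen as the smallest that make the statistical
assertions stable: 20,000-sample cohorts for recovery checks (Monte-Carlo
error well inside the stated ±0.06–0.08 tolerances), 50,000 variants for
the 0.1% heterogeneity-filter rate, 5,000 samples / 2,000 variants / 20×5
CV for the demo pipeline. Passing tests demonstrate internal correctness
and calibration of the machinery on data with the assumed structure; they
do not demonstrate that real genotype panels satisfy that structure
(real LD is not block-AR(1), real lifestyle is not MCAR, and real stage
assignment is not a threshold on a Gaussian liability).

## Known limitations

* Single-ancestry LD reference (the target panel); no external reference
  panel shipped.
* Fixed-effects meta-analysis only; no random-effects or sample-size
  weighted pooling.
* Bayesian genome-wide shrinkage scores (continuous-shrinkage priors) are
  treated as an external method and not reimplemented; the weight-table
  reader accepts their output.
* Unconditional logistic weight estimation for matched designs.
* The additive-interaction dichotomization (top 20% vs rest for both
  scores) is one convention; the functions accept any externally supplied
  ORs and covariance.
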