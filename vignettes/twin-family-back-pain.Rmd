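---
title: "Twin-family analysis of binary pain traits: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Twin-family analysis of binary pain traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinfam)
```

This vignette documents the statistical content of twinfam: the similarity
measures and their variances, the family and association regressions, the
liability-threshold generator and its calibration, the numerical choices
made where the design was genuinely open, and what the test suite does and
does not establish about real data.

## The classical twin design for binary traits

Monozygotic (MZ) twins share essentially all segregating genes; dizygotic
(DZ) twins share half on average. Under the equal-environments assumption,
greater MZ than DZ similarity for a trait is evidence of genetic influence.
For a binary trait observed on complete twin pairs we tally, per zygosity,
`Nc` pairs with both members affected, `Nd` with exactly one, and `N00` with
neither; pairs with either member missing are excluded before counting (and
logged). Three similarity measures are computed from these tallies.

**Casewise concordance.** `C = 2Nc / (2Nc + Nd)` estimates the probability
that the co-twin of an affected individual is affected. Its variance is
estimated by `Var(C) = 4 Nc Nd (Nc + Nd) / (2Nc + Nd)^4`, with a normal
95% interval truncated to [0, 1]. This estimator reproduces the intervals
of the published MZ rows it was validated against to the printed precision;
one published DZ lower bound differs by a single rounding unit (0.12 vs
0.13), which the tests treat as print rounding with a ±0.01 band.

**Double entry, phi and the within-pair odds ratio.** Tabulating each pair
twice — each member once as index and once as co-twin — gives the symmetric
table `(a, b, c, d) = (2Nc, Nd, Nd, 2N00)`. The phi coefficient
`(ad − bc)/√((a+b)(c+d)(a+c)(b+d))` is the Pearson correlation of the two
binary indicators; the odds ratio `ad/(bc) = 4 Nc N00 / Nd²` measures
within-pair association with the Woolf log-scale variance
`1/a + 1/b + 1/c + 1/d`. Double entry is used precisely because it
reproduces, from the published pair tallies, every published point estimate
(odds ratios 9.72/3.53 and 8.95/2.34; correlations 0.39/0.17 and 0.34/0.09)
and every published Woolf interval; this back-validation is frozen into the
acceptance tests.

**Interval for phi.** The published source does not state the method behind
its correlation intervals, and no standard construction we examined
(including the Fisher z-transform used here, with `n` equal to the number
of pairs) reproduces them. twinfam therefore documents Fisher-z as its
choice and deliberately asserts nothing about those printed intervals or
the correlation-difference p-values; they remain an open point.

**Zygosity comparison.** MZ−DZ differences are tested by
`z = (g(MZ) − g(DZ)) / √(var_MZ + var_DZ)` on each measure's working scale
(identity for C, Fisher-z for phi, log for OR), with a one-sided upper-tail
p (alternative: MZ more similar) and a doubled two-sided p. From the
published tallies this reproduces the printed one-sided concordance p of
0.008 for lifetime low back pain and the printed odds-ratio p-values
(0.012, 0.006) exactly; for current thoracolumbar pain the one-sided value
computes to 0.0053, consistent with the printed two-sided 0.011 (which is
reproduced) and with the printed one-sided 0.006 only after rounding the
doubled value — the tests assert exactly what the arithmetic supports.

**Zero cells.** A zero discordant or concordant cell makes the odds ratio
undefined. The default is an explicit error; an optional Haldane–Anscombe
0.5 correction (`continuity = "haldane"`) is off by default because silent
corrections distort small simulations.

**Report rounding.** Report tables round half-up — concordance and
correlation to 2 decimals, odds ratios to 3 significant figures, p-values
to 3 decimals — matching the published style; internal values keep full
precision.

## Family analysis

One twin per pair is selected at random (seeded, logged, and reproducible;
the global RNG stream is never disturbed) and the child's trait is
regressed on the same trait of each family member by ordinary logistic
regression. The analysis is repeated with the co-twins as outcomes and the
two arm estimates are combined by inverse-variance weighting:
`logOR = Σ wᵢ logORᵢ / Σ wᵢ`, `var = 1/Σ wᵢ`, `wᵢ = 1/varᵢ`. Whether the
published per-relative table used a single random arm or an IVW combination
of both is not fully explicit in the source; the package defaults to IVW
(`combine = TRUE`) with a single-arm mode available, so either reading can
be reproduced.

The covariate policy follows the stated "adjusted for age and gender, if
significant": the fit includes the candidate covariates, then drops any
with Wald p ≥ 0.05 and refits, recording the applied set in the result.
Separation and other degeneracies are flagged (`converged = FALSE`), never
silently reported.

## Association tables

For a back-pain outcome against region or condition predictors, one
univariate fit per predictor and a single joint multivariable fit
containing all predictors are produced; a predictor is flagged "retained"
when its multivariable p < 0.05. The multivariable model is a one-shot
joint fit, not stepwise selection — the simplest reading consistent with
footnote-style retention flags. Design points:

* Pooled twin-and-sibling analyses use a logistic model with a per-family
  random intercept, fitted by adaptive Gauss–Hermite quadrature with 15
  nodes (lme4). A per-family rather than per-pair intercept is used when
  twins and siblings are pooled; the alternative is not distinguishable
  from the published description.
* Parent analyses are ordinary logistic regressions and are not
  age-adjusted by default (the source specifies age adjustment only for
  offspring); a `covariates` argument switches this.
* For region predictors the outcome's own region(s) — lower back for the
  lifetime outcome, lower and middle back for the thoracolumbar outcome —
  are removed both from the predictor list and from the "multiple sites"
  count, which flags pain in two or more non-outcome regions.
* Predictors with fewer than `min_count` (default 10) positive individuals
  are dropped with a logged reason, mirroring the published low-number
  exclusions.
* No multiple-testing correction is applied by default, matching the
  published presentation; `p_adjust` accepts any `stats::p.adjust` method.
* A boundary (singular) random-intercept fit — zero estimated cluster
  variance — is treated as a valid limiting case; in that limit the
  coefficients provably coincide with the ordinary logit and the tests
  assert it to 1e-4 on the log-odds scale.

The positive-control diagnostic (`expected_cross_trait_check()`) fits the
lifetime trait as a predictor of the current trait per population; under
shared liability it must produce a strongly positive odds ratio.

## The synthetic cohort generator

No raw cohort is distributable, so the generator's defaults *are* the study
conditions the pipeline is tested under: 651 families, 42.2% MZ; a first
sibling in 64.5%, a mother in 98.3% and a father in 86.9% of families; ages
truncated-normal per role (twins mean 15.3, sd 2.42 on 6–20, both twins
sharing one age; siblings 15.7/4.61 on 4–36; mothers 46.3/4.93 on 30–64;
fathers 48.7/5.78 on 35–78); offspring prevalences 12.1%/9.6–10% and
parental prevalences 42.0%/39.9% and 26.6%/23.1% for the lifetime and
current traits respectively.

**Liability model.** Each trait has a standard-normal liability; a person
is a case when liability exceeds `Φ⁻¹(1 − prevalence)` for their role. The
familial correlation matrix sets MZ co-twins at `a² + c²`, DZ co-twins and
sibling pairs at `a²/2 + c²`, parent–offspring at `a²/2`, and spouses at 0
(no assortative mating, no dominance). Parents receive their own
thresholds rather than an age extrapolation, because adult prevalences
near 40% are far above any child-age extrapolation.

**Calibration.** The variance shares were solved once from the published
concordances through the orthant oracle: the MZ/DZ liability correlations
implied by concordances 0.48/0.25 at prevalence 12.1% are 0.687/0.321,
giving `a² = 2(r_MZ − r_DZ) ≈ 0.73` with `c² = 2r_DZ − r_MZ` slightly
negative; c² is clipped to zero and `a² = 0.69 ≈ r_MZ` adopted (implying
r_DZ = 0.345, within sampling error of 0.321). The current-pain trait
yields `a² = 0.65`, `c² = 0` the same way. The cross-trait loading 0.748
was solved so the within-person lifetime→current odds ratio is 17.7, the
magnitude reported for the study's own positive control; the realized
simulated value is slightly higher (~19) because both traits also share
the age effect, which the loading solver deliberately ignores — well
within the loose ±30% with which this anchor is checked.

**Age.** The reported per-year odds ratios (1.24 lifetime, 1.15 current)
enter through the standard probit bridge `β = log(OR)/1.7`. The age term
`β(age − mean)` joins the liability and the threshold is inflated to
`Φ⁻¹(1 − q)·√(1 + β² var(age))` with the *exact truncated-normal* age
moments, so marginal prevalences stay on target. Because co-twins share
one age, the age term contributes `β² var(age)` to the pair covariance;
`theoretical_similarity()` integrates over the shared age numerically and
is therefore an exact oracle for the generator, not an approximation.

**What the generator does not emulate.** Questionnaire measurement error,
non-MCAR missingness (the optional mask is MCAR only), assortative mating,
sibling age ordering within families, sex effects on prevalence (the study
found none), and item-level condition responses (conditions are emitted as
classified indicators). Passing tests therefore demonstrate correctness of
the estimators under a well-specified liability model — not robustness to
the measurement pathologies of real questionnaire data.

## Numerical choices and degenerate inputs

* Orthant probabilities use mvtnorm's bivariate-normal algorithm; the
  age-integrated oracle uses adaptive 1-D quadrature at rel.tol 1e-8/1e-9.
* `plant_cross_trait_effect()` root-finds the loading with `uniroot` at
  tolerance 1e-9 and verifies the achieved odds ratio to 1e-3, erroring on
  unattainable targets.
* Undefined estimates (no affected individuals; zero double-entry margins;
  zero cells without continuity correction) raise classed errors rather
  than returning NaN; degenerate zygosity tests (zero combined variance)
  likewise.
* Tristate questionnaire fields never coerce unparseable or absent answers
  to "control"; they become missing and are counted in the read log.
  Records excluded for disease/serious-injury attribution keep their rows,
  flagged `analysis_excluded`, so stage-by-stage denominators reconcile
  (loaded = analysed + excluded).
* Half-up rounding is used for report tables because banker's rounding
  disagrees with printed epidemiological tables at .5 boundaries.

## Problem sizes used by the test suite

As the package's own verification scale: oracle-equivalence runs use 50,000
simulated pairs per zygosity; random-intercept parameter recovery uses 800
families × 20 replicates per planted odds ratio (1, 2, 3); the null
MZ/DZ rejection-rate check uses 200 seeds × 1,000 twins-only families; the
Monte-Carlo check of the orthant oracle uses 10⁶ pair draws. All
Monte-Carlo assertions use ±3 Monte-Carlo standard errors.

## Known limitations

* The phi-correlation interval method is a documented package choice that
  does not match the (unstated) method behind the published intervals.
* Variance-component *fitting* (ACE/ADE structural-equation modelling) and
  heritability point estimates are deliberately out of scope: the design
  infers genetic influence from MZ/DZ comparison only.
* The 21-site body-map vocabulary is a documented synthetic stand-in: only
  the lower-limb constituents of the original instrument are published.
* The sensory-sensitivity scale is validated against its declared 5–35
  range even though seven 1–5 items imply a 7–35 minimum; the discrepancy
  is inherited from the instrument description and recorded, not resolved.
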