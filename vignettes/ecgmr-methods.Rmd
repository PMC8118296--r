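---
title: "Methods: mendelian randomisation of ECG intervals on atrial fibrillation risk"
author: "ecgmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mendelian randomisation of ECG intervals on atrial fibrillation risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgmr)
```

## The scientific problem

Electrocardiographic (ECG) intervals — P-wave duration (atrial
depolarisation), PR interval (atrial depolarisation plus atrioventricular
conduction) and QT interval (ventricular depolarisation–repolarisation) —
are associated with atrial fibrillation (AF) in observational cohorts, but
those associations are confounded by age and cardiac comorbidity and are
vulnerable to reverse causation (having AF, or being treated for it,
changes the ECG). Mendelian randomisation (MR) side-steps both problems by
using genetic variants, fixed at conception, as instruments for lifelong
differences in the intervals.

`ecgmr` implements the full analysis this design requires:

1. **Instrument selection** — genome-wide significance filtering
   (`gw_significance_filter()`, strict *P* < 5×10⁻⁸), greedy LD clumping
   (`ld_clump()`, r² < 0.01 within ±250 kb), allele harmonisation to the
   interval-lengthening allele (`harmonise()`), and ion-channel gene
   subsetting (`ion_channel_subset()`).
2. **Allele scores and instrument strength** — `build_score()`,
   `variance_explained()`, `f_statistic()`, `analytic_power()`.
3. **Individual-level association** — covariate-adjusted linear and
   logistic regression (`linear_assoc()`, `logistic_assoc()`), per-5 ms
   scaling (`scale_per_5ms()`), quintile contrasts with floated variances
   (`quintile_contrasts()`), second-score adjustment
   (`adjusted_for_second_score()`).
4. **Summary-data estimators** — Wald ratio, fixed/random-effects IVW,
   MR-Egger, weighted median, weighted mode, MR-PRESSO
   (`mr_ivw()`, `mr_egger()`, `mr_weighted_median()`,
   `mr_weighted_mode()`, `mr_presso()`), fixed-effects meta-analysis
   (`mr_meta_fixed()`) and a bidirectional check (`mr_bidirectional()`).
5. **A synthetic-data generator** (`sim_config()`, `simulate_cohort()`,
   `make_summary_pairs()`) that reproduces the statistical structure of a
   large genotyped cohort, so every stage is testable without access to
   individual-level biobank data.

`run_pipeline()` orchestrates the sequence end to end and writes a
reproducible, schema-versioned result bundle.

## The causal model and its estimators

For variant $j$ with per-allele effect $w_j$ (ms) on the interval $X$, the
allele score is $S_i = \sum_j w_j g_{ij}$. Individual-level analyses fit

$$\operatorname{logit} P(Y_i = 1) = \alpha + \beta S_i + \gamma^T C_i,$$

with covariates $C$ (sex, genotyping array, principal components); $\beta$
is the log odds ratio of AF per ms of genetically predicted interval, and
results are reported per 5 ms ($\mathrm{OR} = e^{5\beta}$).

With two-sample summary statistics $(\hat\beta_{Xj}, \hat\beta_{Yj})$ the
estimators are the standard summarised-data suite. Fixed-effects IVW is
weighted least squares through the origin with weights
$w_j = 1/\mathrm{se}(\hat\beta_{Yj})^2$:

$$\hat\beta_{\mathrm{IVW}} =
  \frac{\sum_j w_j \hat\beta_{Xj}\hat\beta_{Yj}}
       {\sum_j w_j \hat\beta_{Xj}^2},\qquad
  \mathrm{se}_{\mathrm{fixed}} = \Big(\sum_j w_j \hat\beta_{Xj}^2\Big)^{-1/2},$$

with the random-effects SE inflated by
$\sqrt{\max(1, Q/(J-1))}$ (Cochran's $Q$). MR-Egger adds a free intercept
(the directional-pleiotropy estimate) with the same weights and a
multiplicative overdispersion floored at 1. The weighted median
interpolates the weighted empirical distribution of ratio estimates at
cumulative weight 0.5 (weights $\hat\beta_{Xj}^2/\mathrm{se}_{Yj}^2$); the
weighted mode maximises a Gaussian-kernel weighted density of the ratios
with a modified-Silverman bandwidth ($0.9\,\min(\mathrm{sd},\mathrm{mad})
\, J^{-1/5}$, scaled by `bandwidth_factor`; a ×0.5/×1/×2 sensitivity sweep
is attached to every fit). Median and mode SEs come from a parametric
bootstrap (effects redrawn from normals centred on their estimates; 1,000
draws and a mandatory seed by default). Ratio SEs are first-order
(exposure-side error ignored), matching the standard summarised-data
formulation.

MR-PRESSO computes the weighted leave-one-out residual sum of squares and
compares it with a null distribution built by regenerating the summary
data from the leave-one-out IVW fits (1,000 simulations by default);
per-variant outlier p-values are Bonferroni-corrected, the corrected
estimate is IVW on the non-flagged variants, and the distortion test uses
removals of random subsets of the same size as the flagged set.

### Floated variances

Figures that display one odds ratio per score quintile need a confidence
interval for *every* group, including the reference. The floated-variance
reparameterisation assigns each group $g$ a variance $\lambda_g$ such that
$\lambda_i + \lambda_j \approx \operatorname{Var}(\hat b_i - \hat b_j)$
for all pairs. Because the original formulation of this technique leaves
the algorithm open, `quintile_contrasts()` uses an explicit covariance
heuristic: contrasts against the fitting reference are reproduced exactly
for any $\lambda_0$ (since $\operatorname{Var}(\hat b_i) = \lambda_0 +
(\operatorname{Var}(\hat b_i) - \lambda_0)$), so $\lambda_0$ is chosen by
one-dimensional minimisation of the worst relative error over the
non-reference pairs, where the error is $2(V_{ij}-\lambda_0)$ against the
true contrast variance. The attained maximum relative error is reported
on every call (typically <1% on well-conditioned quintile designs; the
acceptance suite enforces <10%), and the two-group case is exactly
identified. Additive display constants (e.g. 93.5 ms for a PR score)
affect `quintile_display()` output only, never any estimate.

### Instrument strength and power

For the one-regressor allele score, $F = r^2(n-2)/(1-r^2)$, with $F > 10$
the conventional weak-instrument bound. Analytic power for a binary
outcome uses the normal approximation

$$\mathrm{power} = \Phi(\lambda - z_{1-\alpha/2}) +
  \Phi(-\lambda - z_{1-\alpha/2}), \qquad
  \lambda = |\log \mathrm{OR}_\mathrm{alt}|\sqrt{n\,r^2\,K(1-K)},$$

where $K$ is the case fraction and $\mathrm{OR}_\mathrm{alt}$ is per SD of
the interval. The two-term form was chosen deliberately: it equals
$\alpha$ exactly at the null (a one-term version gives $\alpha/2$), while
being numerically indistinguishable away from it. The formula is
validated against Monte-Carlo rejection rates (agreement within ±0.05 at
n = 20,000, r² = 0.05, OR 1.3/SD over 500 simulated cohorts) rather than
against any external reference, since published power calculations of
this design typically live in supplements.

```{r power}
# cohort-scale inputs: r2 = 5%, 278,792 participants, 19,132 cases
analytic_power(r2 = 0.05, n = 278792, case_fraction = 19132 / 278792,
               or_alt = 1.15, alpha = 0.05)
```

## What the generator emulates — and what it does not

`simulate_cohort()` produces the stated world the tests run in:

* **Genotypes** in exact Hardy–Weinberg proportions, `rbinom(2, f)` per
  variant; optional LD blocks via a Gaussian-copula latent-haplotype
  construction (two thresholded correlated haplotypes per individual),
  which keeps HWE margins exact while giving a tunable within-block
  allelic correlation.
* **Variant panels** (`simulate_variant_table()`) drawn from the
  *selected* tail: on the allelic-SD scale the smallest effect is the one
  detectable at *P* < 5×10⁻⁸ in an emulated discovery study
  (n = 90,000, phenotype SD 27 ms), with an exponential excess above the
  threshold and per-allele ms effects scaling as $1/\sqrt{2f(1-f)}$.
  An unselected effect distribution would plant near-null "instruments"
  that no genome-wide-significance selection could have produced, and
  their pathological ratio estimates would misrepresent every downstream
  estimator.
* **Exposure** $X_i = c + S_i + \varepsilon_i$, with the noise variance
  set so the score explains `target_r2` of the exposure variance and the
  weights rescaled to a configured population SD. Defaults are the
  PR-interval scenario: 52 variants, r² = 5.0%, mean 163 ms, SD 27 ms.
* **Outcome** logistic in the centred exposure, with the intercept solved
  numerically for a marginal prevalence of 19,132/278,792 ≈ 6.9%
  (population sampling, no case-control ascertainment, matching the
  cohort design); a latent standard-normal confounder and per-variant
  direct (pleiotropic) log-odds effects are available for
  assumption-violation scenarios. Principal-component-like covariates are
  standard normal and null by default.
* **Two-sample structure** by disjoint 50/50 cohort splits
  (`make_summary_pairs()`): per-variant exposure betas by simple linear
  regression in one half, outcome log-ORs by per-variant logistic
  regression in the other. The per-variant logistic fits use a vectorised
  Newton–Raphson scan validated against `glm()` to 10⁻⁶, purely for
  runtime.

Not emulated: realistic genome-wide LD maps, imputation or phasing, sex
chromosomes, relatedness, covariance among principal components, and
case-control sampling. A green test therefore establishes the statistical
machinery — estimator algebra, calibration, orientation and reporting
conventions — not robustness to population-structure artefacts of real
biobank data.

## Numerical and design choices

* **Seeds everywhere**: a `sim_config` seed makes cohorts bit-identical;
  bootstrap and MR-PRESSO seeds are mandatory arguments;
  `run_pipeline()` derives stage seeds from its master seed, so two runs
  of one configuration hash identically.
* **Quintiles** are computed from ranks (ties broken by stable input
  order) within a reference subset — the non-cases, so the case mix does
  not shift the grid — and the resulting cut-points are applied to
  everyone; ties at a cut-point fall to the lower group.
* **Harmonisation** resolves direct, allele-swapped, strand-complement
  and swapped-complement reporting; palindromic variants (A/T, C/G) with
  effect-allele frequency in [0.42, 0.58] are dropped as ambiguous; every
  drop carries a machine-readable reason. Orientation to the
  interval-lengthening allele (all exposure betas ≥ 0) is the contract
  MR-Egger requires.
* **Clumping** is greedy in ascending p-value; a missing r² for an
  in-window pair is treated as r² = 1 (conservative removal) and logged.
* **Wald everything**: CIs are $\hat\beta \pm 1.96\,\mathrm{se}$ on the
  estimation scale, p-values are two-sided normal, and
  `wald_p_from_or_ci()` inverts exactly this convention, so reported
  OR/CI/p triplets round-trip.
* **Significance flags** at *P* < 0.01 (significant) and *P* < 0.05
  (suggestive) annotate every result object and output table; they never
  alter estimates.
* **Degenerate inputs** fail loudly: zero-variance scores, rank-deficient
  designs (naming the collinear columns), detected separation,
  single-class outcomes, constant exposure betas in Egger, all-variant
  outlier flags in MR-PRESSO, mixed scales in meta-analysis.

## Known limitations

* **MR-Egger under finite instrument strength.** When exposure effects
  are re-estimated in a 50,000-sample split, the instrument panel's
  $I^2_{GX} \approx 0.89$, and the Egger slope attenuates toward zero by
  roughly the measurement-error factor (≈11% from $1 - I^2_{GX}$, plus
  ≈2% logistic non-collapsibility). The package's 200-replicate recovery
  study measures ≈18% attenuation — several Monte-Carlo SEs — while IVW,
  weighted median and weighted mode stay within 2 Monte-Carlo SEs of the
  causal parameter. This is a documented property of MR-Egger, not an
  implementation artefact; the SIMEX correction that addresses it is out
  of scope. With published discovery-scale exposure statistics
  (n ≈ 92,000) the attenuation is correspondingly smaller.
* **First-order ratio SEs** ignore exposure-side sampling error, the
  standard convention for summarised data; weak-instrument worlds inherit
  the usual mild anti-conservatism.
* The floated-variance construction is a covariance heuristic: its error
  bound is *surfaced* (`max_rel_error`) rather than hidden, but pairwise
  CIs for non-reference pairs are approximate by design.
* The bidirectional stage quantifies reverse causation as the
  dimensionless loop gain $|\beta_{\mathrm{rev}}\,\beta_{\mathrm{fwd}}|$
  (ms per log-odds × log-odds per ms); it assumes the liability panel
  affects the outcome directly and the interval only through the
  configured reverse path.

## A small worked example

```{r example}
cfg <- sim_config(n_individuals = 20000,
                  variants = simulate_variant_table(52, seed = 1),
                  seed = 7)
cohort <- simulate_cohort(cfg)
cohort

score <- build_score(cohort$genotypes,
                     setNames(cohort$variants$beta, cohort$variants$id))
variance_explained(score, cohort$exposure)

pairs <- make_summary_pairs(cohort)
mr_ivw(pairs, "fixed")
scale_per_5ms(mr_ivw(pairs, "fixed"))
```
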