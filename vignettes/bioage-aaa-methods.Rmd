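---
title: "Biological age acceleration, polygenic risk and incident disease: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Biological age acceleration, polygenic risk and incident disease: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioagerisk)
```

## The scientific problem

Abdominal aortic aneurysm (AAA) is a degenerative vascular disease of
later life. Chronological age is a crude proxy for the cumulative
physiological decline that drives it; *biological age* scores built from
blood-chemistry panels aim to capture that decline directly. This package
implements the full analytic chain used in cohort epidemiology to ask three
questions: does biomarker-measured accelerated ageing predict incident AAA
beyond chronological age; how does it combine with inherited risk measured
by a polygenic risk score (PRS); and how much of smoking's damage travels
through accelerated ageing?

Everything is exercised against a synthetic cohort generator whose
parameters are fully exposed, so each estimator can be validated by
parameter recovery rather than by faith.

## Biological age measures

### Klemera-Doubal biological age (KDMAge)

Nine markers enter: FEV1, systolic blood pressure, albumin, alkaline
phosphatase, blood urea nitrogen, creatinine, C-reactive protein, glycated
haemoglobin and total cholesterol. For each marker $i$ an OLS regression of
the marker on chronological age (fit separately for men and women) yields
intercept $q_i$, slope $k_i$ and residual RMSE $s_i$. The estimator is a
precision-weighted average of the per-marker age predictions and
chronological age:

$$\mathrm{KDMAge}
  = \frac{\sum_i (x_i - q_i)\,k_i/s_i^2 + CA/s_{BA}^2}
         {\sum_i (k_i/s_i)^2 + 1/s_{BA}^2}.$$

$s_{BA}^2$ is estimated as the sample variance of the fitted values from a
multiple OLS of chronological age on all nine markers — the variance in age
explained by the biomarker set. The classical Klemera-Doubal small-sample
correction term is not applied; the verbal definition above is what
`fit_kdm_model()` implements, and the direction of the per-marker
regressions is biomarker-on-age, which is the only direction consistent
with the estimator's $(x_i - q_i)k_i/s_i^2$ structure.

Two limits pin the implementation: inputs lying exactly on the fitted
biomarker-age lines return the input age to $10^{-9}$, and $s_{BA}
\to \infty$ reduces a single-marker model to $(x - q)/k$.

### Phenotypic age (PhenoAge)

PhenoAge maps nine blood-chemistry markers plus chronological age through a
fixed published linear predictor $xb$ (C-reactive protein enters as its
natural log, floored at 0.01 mg/dL), a Gompertz mortality-risk transform,
and back to an age scale:

$$\text{risk} = 1 - \exp\!\left(-\tfrac{1.51714\, e^{xb}}{0.0076927}\right),
\qquad
\text{PhenoAge} = 141.50 + \frac{\ln(-0.00553 \ln(1-\text{risk}))}{0.09165}.$$

The coefficients are immutable defaults in `phenoage_coefficients()`.
Numerically, $1-\text{risk}$ underflows to zero in double precision once
$xb \gtrsim -1.3$, so `compute_phenoage()` evaluates the second transform
as $\ln(0.00553\,z)$ with $z = 1.51714\,e^{xb}/0.0076927$ — identical in
exact arithmetic, stable everywhere the exponential itself is
representable. The implementation is pinned against an independent
50-digit evaluation of the closed form at a reference vector.

Units follow the published model: albumin g/L, creatinine µmol/L, glucose
mmol/L, CRP mg/dL, lymphocyte %, MCV fL, RDW %, ALP U/L, WBC 10⁹/L.

### Age acceleration

`compute_acceleration()` regresses biological age on chronological age over
the analysis sample (pooled across sexes by default; a `by` argument allows
stratification) and returns the residual. A strictly positive residual is
*accelerated* ageing; zero or less is not. By construction residuals are
mean-zero and uncorrelated with chronological age on the fitting sample.

## Polygenic risk

The weighted score over $N$ variants with per-allele log odds ratios
$\beta_i$ and dosages $d_i \in [0,2]$ is

$$\mathrm{PRS} = \sum_i \beta_i d_i \cdot \frac{N}{\sum_i \beta_i},$$

so equal weights collapse it to a risk-allele count and rescaling all
$\beta$ leaves it unchanged — both enforced as property tests. Tertiles of
the score define low/intermediate/high genetic risk; a score exactly at a
cut point goes to the lower group, making assignment deterministic under
ties. The shipped 31-variant weight table is a synthetic stand-in with the
shape of a GWAS-derived file (see `inst/extdata/prs_weights_synthetic.tsv`).

## Survival machinery

All hazard models are Cox partial-likelihood fits (Efron ties) through the
`survival` package, with Wald intervals on the log-HR scale. On top of
that:

* **Quartile trend** — the exposure is replaced by its within-sample
  quartile index coded 1-4 and entered as one continuous covariate.
* **Dose-response** — a restricted cubic spline with three knots at the
  25th/50th/75th percentiles, Harrell's truncated-power basis normalized by
  $(t_3-t_1)^2$ (written in this package; no installed package provides the
  restricted basis). The curve is anchored at HR = 1 at the sample median;
  non-linearity is the Wald test on the restricted term.
* **Proportional hazards** — scaled Schoenfeld residual tests via
  `survival::cox.zph`.
* **Competing risks** — Fine-Gray subdistribution fits via
  `survival::finegray` with Kaplan-Meier censoring weights; with zero
  competing deaths they coincide with the cause-specific fits to $10^{-6}$,
  which is tested.
* **Landmark filtering** — follow-up restarted at a configurable landmark
  (default 2 years), earlier events and censorings removed.

Type-I error of the trend, non-linearity and proportional-hazards tests is
checked against the exact binomial 99% band at 200 null replicates; Cox
recovery of a known binary log-HR of 0.5 at n = 20,000 is checked for bias
(±0.03) and CI coverage.

## Interaction and mediation

Additive interaction between accelerated ageing and high genetic risk uses
the four-level cross-classification (reference: neither), giving component
hazard ratios $HR_{10}, HR_{01}, HR_{11}$ and

$$\mathrm{RERI} = HR_{11} - HR_{10} - HR_{01} + 1, \qquad
  \mathrm{AP} = \mathrm{RERI}/HR_{11}.$$

The cross-classified parameterization is algebraically identical to
main-effects-plus-product but matches how joint HR tables are reported and
simplifies resampling. Confidence intervals are percentile bootstrap over
participants (default 1000 replicates, seeded); zero outside the interval
indicates additive interaction. Multiplicative interaction is the
likelihood-ratio test between Cox models with and without the product term.

Mediation of pack-years of smoking through age acceleration combines an OLS
mediator model and a Cox outcome model. Effects are expressed on the
event-probability scale at a fixed horizon (default: mean follow-up) per
additional pack-year: potential mediator values under exposure $x$ and
$x+1$ are simulated with shared Gaussian draws and the model-implied risk
differences averaged, giving the indirect effect (IE), direct effect (DE)
and proportion mediated IE/(IE+DE). The probability scale (rather than
log-hazard) is chosen because reported effect decompositions of this kind
have magnitudes of order $10^{-5}$ per pack-year — a risk-difference, not a
hazard, scale. The rare-outcome approximation underlying the Cox-based risk
computation is guarded by a warning above a 5% event fraction. P-values
come from a nonparametric percentile bootstrap (participants resampled with
replacement, unstratified).

## The synthetic cohort generator

`simulate_cohort()` draws, per participant: sex (54.1% female); age from a
normal(56.4, 8.1²) truncated to 37-73 years; pack-years from a
zero-inflated gamma with P(0) = 0.556 (the never-smoker mass point) and
gamma(1.5, scale 12) otherwise; 14 biomarkers linear in age with sex
offsets, per-pack-year smoking displacement and Gaussian noise
(`default_biomarker_specs()`; means and slopes are plausibility choices for
a middle-aged European cohort — no public source provides them); 31
genotype dosages Binomial(2, freq); and latent event and death times from
independent exponential hazards with log-linear predictors, administrative
censoring at 13.68 years, first event recorded. CRP is truncated below at
0.005 mg/dL so the log transform is defined; parameters keep the truncated
mass below 0.1%.

The *true acceleration* driving the hazard is the deviation of the nine KDM
biomarkers from their sex- and age-expected values projected through the
KDM precision weights implied by the generating parameters
(`kdm_truth_projection()`). Its smoking-driven component,
$\gamma \times$ pack-years, is exposed separately; the full deviation
(including biomarker noise) must enter the hazard, because a hazard loading
only on the smoking component would make the mediator coefficient zero
given exposure and the indirect effect unidentifiable.

Default hazard coefficients are set so that the generated cohort reproduces
the anchor statistics of a large population study of AAA: expected
incidence 1886/350,483 ≈ 0.54% by the censoring horizon (the baseline rate
is solved deterministically against the drawn covariates when
`target_incidence` is set), acceleration per-SD hazard ratio ≈ 1.06, and a
high-vs-low PRS tertile hazard ratio ≈ 1.7. With the defaults the implied
proportion of the smoking effect mediated by acceleration,
$\beta_a\gamma/(\beta_a\gamma + \beta_p)$, is ≈ 9.7%;
`calibrate_mediation()` rescales the direct path to hit any target exactly.

What the generator does **not** emulate: linkage disequilibrium between
variants, calibrated national demographics, longitudinal biomarker
trajectories, and a PhenoAge-specific hazard pathway — the hazard loads on
the KDM projection, so PhenoAge acceleration (which shares only four
markers) shows attenuated associations in synthetic data. Passing recovery
tests therefore demonstrate estimator correctness under the assumed
structure, not fidelity of any real-world effect size.

## Problem sizes and numerical choices

Recovery and operating-characteristic suites use sizes at which Monte-Carlo
error is small relative to the tolerance being asserted: marginal-structure
checks at n = 50,000 (3-SE bands); Cox recovery at n = 20,000 × 100
replicates; size checks at 200 replicates against the exact binomial band;
RERI power at n = 50,000 with a 1000-replicate bootstrap. The mediation
recovery test calibrates the generator to a 10% proportion mediated and
uses a 4% incidence with a mediator-path log-HR of 0.1: a delta-method
calculation shows that at the default 0.54% incidence a single
50,000-participant replicate carries a standard error of ~0.11 on the
recovered proportion, an order of magnitude too large to certify a ±5
percentage-point recovery, while the powered design brings it to ~0.01.

Other numerical conventions: percentiles everywhere are linear
interpolation between order statistics (`stats::quantile` type 7);
winsorization is fit-and-apply on the baseline sample, with stored cut
points reused for projection (the exactly idempotent path); quartile and
tertile boundaries send ties to the lower group; acceleration residuals
within $10^{-10}\,\mathrm{sd}$ of zero are snapped to zero so an exact
on-the-line fit classifies as non-accelerated; bootstrap replicates that
fail (an empty cross-class cell after resampling) are dropped and counted.

## Known limitations

* The KDM training sample is the analysis cohort itself (cross-sectional
  calibration); no external reference population is supported.
* Mediation assumes no exposure-mediator interaction and a single mediator.
* The Fine-Gray weights treat administrative censoring as independent.
* Winsorization percentiles are pooled across sexes by default
  (`winsorize_by_sex` switches to stratified; which convention original
  cohort analyses used is generally unstated).
* PRS handling expects dosages already aligned to effect alleles; no VCF
  import or allele flipping is provided.
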