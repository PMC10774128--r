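---
title: "Modeling early-childhood brain growth and cognition: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling early-childhood brain growth and cognition: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subcortgrowth)
```

# The scientific problem

Between birth and school age, intracranial volume (ICV) and the subcortical
gray-matter structures (thalamus, amygdala, hippocampus, caudate, putamen,
globus pallidus) grow rapidly and nonlinearly, and the pace differs by
region. Multisite consortia pool thousands of MRI scans across cohorts that
differ in scanner, segmentation pipeline, age coverage, design
(cross-sectional versus longitudinal) and sociodemographic composition.
This package implements the statistical machinery such a study needs:

1. a hierarchical asymptotic growth model for regional volumes,
2. a maturation-age statistic derived from the fitted curve,
3. heteroscedastic linear mixed models for ICV-scaled volumes and for
   Mullen Scales of Early Learning (MSEL) raw scores,
4. brain–cognition correlation at a common prediction age with a bootstrap
   comparison between full-term and preterm children,
5. product-of-coefficients mediation with bootstrap intervals, and
6. split-sample replication.

Because the real multicohort data of such studies sit behind controlled
access, the package ships a synthetic-cohort generator whose defaults
mirror the statistical structure of an eight-cohort consortium, so every
stage is exercised end to end by ordinary tests.

# The growth model

The expected volume of one region at postnatal age $x$ (days) is the
asymptotic (Gompertz-rate) function

$$f(x;\theta) = \theta_1 + (\theta_2 - \theta_1)\, e^{-e^{\theta_3} x},$$

where $\theta_1$ is the asymptote (plateau volume, mm³), $\theta_2$ the
intercept (volume at birth, mm³) and $e^{\theta_3}$ the per-day rate
constant. The curve equals $\theta_2$ at birth and approaches $\theta_1$
monotonically. One parameterization subtlety deserves a note: with the
rate written inside the double exponential as $e^{\theta_3 x}$ the curve
cannot reproduce tabulated maturation ages from published reference
parameters, while the rate-constant form $e^{-e^{\theta_3}x}$ reproduces
all of them; the package therefore uses the latter throughout.

Asymptote and intercept are hierarchical:

$$\theta_{jk1} = \theta_1 + \textstyle\sum_k \beta_{k1} x_{jk} + u_{j1},
\qquad
\theta_{jk2} = \theta_2 + \textstyle\sum_k \beta_{k2} x_{jk} + u_{j2},$$

with binary covariates $x_{jk}$ (male sex, preterm birth, low birthweight,
low maternal education, low family income, and cohort dummies) and
independent zero-mean normal subject effects $u_{j1}, u_{j2}$. The rate
constant $\theta_3$ carries no covariate or random effects — this is
enforced structurally, not by constraint. Residuals are normal with
cohort-specific variances (a reference cohort has ratio 1), the standard
device for multisite scale differences.

## Estimation: profile the rate, solve the rest as a linear mixed model

For fixed $\theta_3$, write $w_{ij} = e^{-e^{\theta_3} x_{ij}}$. The model
becomes *linear*:

$$y_{ij} = (1-w_{ij})\,(\theta_1 + \textstyle\sum\beta_{k1} + u_{j1})
         + w_{ij}\,(\theta_2 + \textstyle\sum\beta_{k2} + u_{j2})
         + \varepsilon_{ij},$$

a linear mixed model with a two-column per-subject random-effect design
$[(1-w), w]$ and grouped residual variances. The fitter (`hetlmm()`)
maximizes the marginal likelihood exactly in the fixed effects and the
overall residual scale (both profiled out in closed form) and numerically
in the remaining variance parameters (two log random-effect sd ratios and
the cohort log sd ratios), using per-subject Woodbury blocks so one
likelihood evaluation is $O(Np)$. The scalar $\theta_3$ is then profiled
over the bracket $[-9, -3]$ — generous around plausible per-day rates —
by a 13-point coarse grid followed by golden-section refinement in the
best sub-bracket.

Numerical choices that matter:

* **Estimation is ML, not REML**, so model variants with different fixed
  effects are comparable by likelihood ratio.
* **Residual quadratic forms are computed from residuals**, never by the
  $y'Wy - 2b'\beta + \beta'A\beta$ shortcut, which cancels catastrophically
  when a cohort variance ratio becomes small during optimization.
* **Warm starts are audited.** Profiling reuses the previous grid point's
  variance parameters as a start, but each warm-started solve is confirmed
  against a neutral start and the better optimum kept; otherwise the
  profile can inherit a poor local basin from an extreme rate value and
  the outer search lands on the wrong rate.
* **Standard errors** are Wald, from the observed information of the
  design augmented with $\partial\mu/\partial\theta_3$, so the reported
  rate-constant uncertainty accounts for its correlation with the other
  fixed effects (variance parameters are held at their ML values). Two-sided
  p-values use the standard normal reference; with thousands of
  observations this is indistinguishable from a t reference, and it is
  documented as an approximation.
* **Random effects are independent** ($u_{j1} \perp u_{j2}$) by default,
  matching the stated independence assumption of the linear models and
  extending it to the nonlinear one; an unstructured covariance is
  available behind `unstructured_re = TRUE` but off by default.
* Two model variants are first class: the full five-covariate model and a
  sensitivity variant excluding family income, which is highly correlated
  with maternal education. Complete-case filtering is applied per model
  and the dropped-row count is logged.

## Maturation age

Maturation age is the age at which the fitted curve reaches 99% of its
asymptote, available in closed form:

$$x_{0.99} = -\frac{\ln\!\big(0.01\,\theta_1 / (\theta_1 - \theta_2)\big)}
                  {e^{\theta_3}}.$$

Ages are reported in years using 365.25 days/year, to one decimal. A curve
already at or above the threshold at birth returns 0 with a warning; a
non-increasing curve is an error. The closed form is tested against a
bisection root-finder on 1,000 random parameter draws to $10^{-6}$ days.

```{r maturation}
truth <- default_truth()
sapply(names(truth$volumes), function(r)
  days_to_years(maturation_age(truth$volumes[[r]]$params), 1))
```

# The linear mixed models

ICV-scaled volumes ($y/\mathrm{ICV}\times 1000$, no age term — the ratio
largely removes the shared growth) and MSEL raw scores (with one shared
linear age slope per scale) are modeled with covariate and cohort fixed
effects, a subject random intercept, and cohort-specific residual
variances, by the same `hetlmm()` engine. Scaling uses the same-visit ICV
measurement; visits lacking ICV are dropped with a logged count. Cohorts
with fewer than 3 observations cannot support their own variance and are
pooled with the reference.

Covariate-by-age interaction tests use the likelihood ratio between
nested ML fits against a chi-square reference; the Wald z of the
interaction coefficient is also emitted for comparison, since the choice
of test is genuinely open.

"Interindividual variation" — the tabulated summary of how much of the
score variance is stable between children — is not a standard quantity,
so the package defines it explicitly as the random-intercept share of
total variance,
$100\cdot\hat\sigma_u^2 / (\hat\sigma_u^2 + \bar\sigma_\varepsilon^2)$,
with $\bar\sigma_\varepsilon^2$ the observation-count-weighted mean of
the cohort residual variances. The definition is isolated in
`interindividual_variation()` so an alternative is one function swap.

# Brain–cognition correlation, mediation, replication

**Panel.** Subject-level predictions of all seven volumes and five scores
at a common age — 730.5 days (age 2, where visit density is highest; the
gross-motor scale is valid only to ~3.5 years) — are assembled from the
fitted models. By default predictions add each subject's empirical-Bayes
(BLUP) random effects to the fixed-effect curve; whether published
analyses used BLUPs or population curves is typically unstated, so a
population-only mode (`include_blups = FALSE`) is provided and the default
documented.

**Correlations.** Pearson correlations within the full-term and preterm
strata, two-sided p-values from the t transform, and a Bonferroni flag at
$0.05/35$ applied to the 7×5 volume–score family. Differences between
strata get percentile bootstrap intervals (default $B = 2000$; stated
bootstrap sizes are used where a published analysis names one, 10,000 for
mediation) over independent case resampling of each stratum. Percentile
rather than BCa intervals are used deliberately — simple, seed-stable and
adequate at these stratum sizes; the choice is isolated and swappable.

**Mediation.** The product-of-coefficients decomposition from two OLS
fits: mediator ~ treatment + covariates and outcome ~ treatment + mediator
+ covariates, giving ACME $= ab$, ADE $= c'$, and total $= ab + c'$, which
for linear models equals the treatment coefficient without the mediator
exactly (asserted to $10^{-8}$ in tests). Intervals are percentile over
case resamples; no multiplicity correction is applied at this stage, by
design. The adjustment set defaults to the remaining sociodemographic
factors; this mirrors the main models but is a package decision, not a
claim about any particular published analysis.

**Replication.** Subjects (never observations) are halved 100 times,
stratified by cohort so each fold retains every site — stratification is
our choice to prevent leakage of repeated measures and empty-site folds.
Per effect we report the proportion of splits with sign agreement and with
sign agreement plus dual Bonferroni significance (necessarily no larger).
Splits that lose a covariate level are redrawn and counted; non-convergent
fold fits drop that repeat from the denominators.

# The synthetic-cohort generator

`default_cohorts()` emulates the structure that makes multicohort infancy
studies statistically awkward: eight sites totalling ~2,100 children with
very unequal sizes (the largest ~1,000, the smallest ~90), three
cross-sectional sites (a neonatal cohort scanned in the first weeks, an
early-infancy cohort, and a preschool cohort seen once at 3–6 years), site
age windows spanning 5–2,250 postnatal days, site-specific covariate
prevalences (e.g. a low-SES birth cohort versus low-risk volunteer
samples), small site mean shifts, and residual sds from 0.8× to 1.4× the
base level. Visit ages are uniform integer days within the site window;
cross-sectional sites have `visits_per_subject = c(1, 1)`. A single seed
drives everything; cohorts are processed in list order and subjects in id
order, so tables are byte-identical across reruns.

`default_truth()` sets the generative parameters. Curve parameters and
covariate effects are the published reference values for this kind of
study (seven regional triples, five effects on each of asymptote and
intercept, five cognitive intercepts with a common 0.03 points/day slope).
Variance components are *not* published, so the generator must choose
them; the choices, made once and documented here, are:

* random-effect sds: 5% of the reference asymptote (for $u_{j1}$) and 5%
  of the reference intercept (for $u_{j2}$) — biologically plausible
  between-child spread for regional volumes;
* base residual sd: 2% of the reference asymptote — segmentation-scale
  measurement noise;
* cognitive scales: total sd 3 raw-score points, split between random
  intercept and residual so the random-intercept share matches the
  tabulated interindividual-variation percentages (21.5%, 10.37%, 6.07%,
  13.12%, 19.05%);
* cohort mean shifts are expressed as *fractions* of the reference
  parameter (±1.5% at most) rather than absolute mm³, because one
  absolute shift cannot serve regions whose volumes span three orders of
  magnitude.

Family income is missing (masked to `NA`) with a site-specific
probability; the true status still drives generation, and downstream
models use complete cases with logged drop counts.

What the generator does **not** emulate: MRI segmentation error structure
(noise is homoscedastic Gaussian within site), twin/family clustering
(the sibling-dropping utility exists but siblings are not generated),
covariate correlation within subject draws (prevalences are independent
Bernoulli), and age-dependent heteroscedasticity. Passing tests therefore
demonstrate that the estimators recover the assumed data-generating
process, not that real segmentation pipelines satisfy these assumptions.

# Problem sizes used by the tests and scripts

The test suite exercises parameter recovery at 500 subjects × 3 visits
over 50 seeds for the ICV column (each parameter within 3 reported SEs of
truth in ≥95% of seeds), bootstrap calibration at 200 replicates of
$B \in [250, 400]$, and the remaining properties at a few hundred
subjects. The analysis scripts under `analysis/` run the full workflow at
the default eight-cohort scale; the growth stage takes a few minutes per
region at that size, and the split-replication stage reduces the growth
model to 10 repeats on one region because each repeat refits the
nonlinear model twice.

# Known limitations

* Wald inference conditions on the ML variance parameters; no
  Satterthwaite or Kenward–Roger correction (and no REML) is provided.
* The rate constant is profiled as a scalar; regions are fitted
  independently, with no cross-region covariance.
* Percentile bootstrap intervals can undercover slightly at small stratum
  sizes; the calibration tests bound this at the sizes used.
* The mediation module assumes linear models without treatment–mediator
  interaction and offers no sensitivity analysis for unmeasured
  confounding of the mediator–outcome path.
* `hetlmm()` supports at most two random-effect columns per subject —
  exactly what the growth model needs — and subject effects only (no
  crossed or nested factors beyond the cohort variance groups).
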