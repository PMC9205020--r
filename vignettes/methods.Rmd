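---
title: "Methods: metal mixtures, biological aging, and osteoarthritis"
author: "metalage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metal mixtures, biological aging, and osteoarthritis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metalage)
```

`metalage` analyzes a cross-sectional cohort with nine urinary metals
(Ba, Cd, Co, Cs, Mo, Pb, Sb, Tl, Tu), two constructed whole-body aging
scores plus telomere length, self-reported osteoarthritis (OA), and a
standard covariate set. This vignette is the package's own account of the
statistical machinery, its assumptions, the choices made where the design
was genuinely open, and what the synthetic-cohort tests do and do not
demonstrate.

## Exposure handling

Concentrations below a metal's limit of detection (LOD) are replaced by
LOD/√2, the conventional substitution for moderately censored biomarkers;
detection rates are reported alongside. Urinary dilution is handled by
creatinine correction — µg/L divided by creatinine in g/L gives µg/g
creatinine — after which metals are Ln-transformed for continuous models
or cut into quartiles at the analysis-sample 25/50/75 percentiles
(weighted percentiles if survey weights are supplied). Quartile intervals
are closed on the right, (−∞, c₁], (c₁, c₂], (c₂, c₃], (c₃, ∞), and
ties that would empty a quartile are an error rather than silently
collapsed. Trend tests refit the model with the quartile replaced by its
integer score 1–4 and report that coefficient's Wald p-value.

## Aging scores

**Klemera–Doubal biological age.** Each biomarker is regressed on
chronological age (CA) by OLS, giving slope $k_j$, intercept $q_j$, RMSE
$s_j$ and signed correlation $r_j$ ($r_j^2$ is the OLS $R^2$; the signed
form is used so the characteristic correlation reflects direction). The
biomarker-only estimate is
$$\mathrm{BA}_E = \frac{\sum_j (x_j - q_j)\,k_j/s_j^2}{\sum_j (k_j/s_j)^2},$$
and the corrected estimator shrinks it toward CA:
$$\mathrm{BA} = \frac{\sum_j (x_j - q_j)\,k_j/s_j^2 + \mathrm{CA}/s_{BA}^2}
{\sum_j (k_j/s_j)^2 + 1/s_{BA}^2},$$
where $s_{BA}^2$ is the residual variance of $\mathrm{BA}_E - \mathrm{CA}$
on the training sample minus a term involving the characteristic
correlation and the CA range. Because BA is a precision-weighted average
of $\mathrm{BA}_E$ and CA it always lies between them; on a noise-free
panel linear in CA it returns CA exactly, which is the package's primary
correctness check.

Two numerical policies deserve note. $s_{BA}^2$ can be negative in small
or weakly age-structured samples; the fit clamps it to a configurable
floor (default $10^{-4}(\mathrm{CA_{max}-CA_{min}})^2$) with a warning,
and scoring falls back to $\mathrm{BA}_E$ if positivity still fails.
Near-deterministic biomarkers ($|r_j| \to 1$) are capped just below 1 so
the characteristic-correlation terms stay finite. Parameters are fitted
on the analysis cohort itself by default — no external reference
population is assumed — but fitted parameters serialize to YAML and can
be supplied externally. Biomarkers are not trimmed or Winsorized before
fitting, and CA enters as exact years (the dichotomized age used as a
model covariate is a separate choice).

**Phenotypic age** is a fixed closed form: a linear predictor over nine
biomarkers plus CA (albumin −0.0336 per g/L, creatinine +0.0095 per
µmol/L, glucose +0.1953 per mmol/L, Ln-CRP +0.0954 per Ln mg/dL,
lymphocyte percent −0.0120, mean cell volume +0.0268 per fL, red-cell
distribution width +0.3306, alkaline phosphatase +0.00188 per U/L,
white-cell count +0.0554 per 10⁹/L, age +0.0804 per year, intercept
−19.907), mapped through a Gompertz-type 10-year mortality transform with
constants 141.50, 0.00553, 1.51714, 0.0076927 and 0.09165. The inner
log-of-exponential pair in the published transform collapses
analytically; the package evaluates the collapsed form, which is
identical in exact arithmetic and avoids underflow at extreme predictor
values, and the tests compare it against a literal nested transcription
to 10⁻¹⁰. The assumed units above are printed in the scoring log, since
unit mix-ups are the dominant failure mode for this formula.

## Regression surfaces

Single-exposure models are ordinary maximum-likelihood fits (`glm`/`lm`)
of OA on each Ln metal or metal quartile, and of each aging marker on the
same exposures, adjusted for the standard covariate set: dichotomized age
(<60/≥60 — the stated covariate coding, even though the aging scores use
continuous age), sex, race/ethnicity, education, family income-to-poverty
ratio, marital status, BMI, physical activity, drinking status, and serum
cotinine. Education is included by default with a toggle, reflecting
ambiguity in the source adjustment set; creatinine is not additionally
adjusted once metals are creatinine-corrected. Missing covariates become
an explicit "missing" factor level (categorical) or are median-imputed
(continuous).

Survey weights, when supplied, enter as prior weights with
quasi-likelihood fitting and heteroskedasticity-robust HC0 sandwich
standard errors. This replaces the full Taylor-linearized survey variance
with its strata and PSUs: the synthetic generator has no design strata,
point estimates are weight-driven, and a hook for externally computed
standard errors covers real-data replication. With constant weights the
estimates coincide with the unweighted fit to numerical precision, which
is tested. FDR correction is Benjamini–Hochberg, applied in the smallest
family consistent with reporting: the nine metals' continuous p-values
together, and the nine quartile trend p-values together, per outcome.

## Weighted quantile sum regression

The mixture effect is modeled as a weighted sum of per-metal quantile
scores (default 4 quantiles), with weights $w \ge 0$, $\sum w = 1$, and
the index coefficient's sign fixed a priori ("positive" for OA, since an
adverse joint effect is the hypothesis). The sample is split 40% training
/ 60% validation (the cited mixture package's defaults; exposed as
configuration along with the bootstrap count, default 100). On each
bootstrap resample of the training split the full constrained likelihood
— including covariates, per the conditional estimation the reference
implementation uses — is maximized with weights reparameterized through a
softmax and the index coefficient through a log link, using BFGS with
analytic gradients; simplex membership therefore holds to machine
precision by construction, and label equivariance (permuting metal
columns permutes weights) is tested rather than assumed. Weights are
averaged across converged bootstraps (an option weights the average by
the bootstrap index z-statistic); fewer than 50% converged bootstraps is
an error. The final inference refits the outcome on the fixed-weight
index in the held-out validation split, so the reported OR per
one-quantile increase is not contaminated by weight estimation.

## Quasi-Bayesian mediation

Parallel mediation fits a linear mediator model and a logistic (or
linear) outcome model, draws `n_sim` (default 1000) parameter vectors
from each fit's asymptotic normal, simulates counterfactual mediator
values — including residual noise — at the exposure contrast (observed
mean vs mean + 1 unit; one quantile for the WQS index), and averages
potential outcomes over the sample. Effects are therefore average risk
differences for binary outcomes, not log-odds products; a
product-of-coefficients reading is recovered exactly in the all-linear
case, which the tests exploit as an oracle. The reported IE and DE
average the two exposure-arm definitions, making TE = IE + DE an exact
identity for the parallel decomposition. Point estimates are draw means,
intervals are 2.5/97.5 percentiles, p-values are two-sided tail
proportions floored at 2/`n_sim`.

Serial mediation (exposure → telomere → whole-body age → outcome) fits
the three-model chain and isolates the path-specific effect by flipping
the exposure only inside the first mediator model and propagating the
change through the second mediator to the outcome, holding everything
else at the control level; in the linear case this is exactly
$a_1 d_{21} b_2$. Parameter draws are independent across the three
component models although the models share data — the standard
normal-approximation block treatment, and a documented limitation.
Counterfactual pairs share residual draws within a simulation, a variance
reduction that leaves the estimand unchanged under additive errors. The
serial TE reported is the full total effect, which exceeds the serial
IE + DE whenever the non-serial paths are active. The proportion mediated
is IE/(IE + DE) in both modes, reported as a percentage, and undefined
(an error) when |IE + DE| is below tolerance — per-draw proportion
intervals are wide whenever the total effect is weak, and should be read
accordingly.

## The synthetic cohort generator

The generator is first-class, tested code. It draws Ln metals from a
multivariate normal whose default correlation structure encodes the
moderate pairs seen in U.S. spot-urine data (Cs–Tl 0.58, Ba–Co 0.41,
Cd–Pb 0.40, weak 0.15 background); the configured covariance lives on the
creatinine-corrected scale, and observed µg/L values add a shared
Ln-dilution term that correction later removes — otherwise shared
dilution would inflate every analysis-scale correlation. Detection limits
default to ~94% detection per metal. A latent mediator age equals CA plus
an acceleration driven by the configured metal effects (defaults: Cd 2.2,
Co 1.0, Cs 0.8, Pb 0.6, Tl 0.3 years per Ln-unit), a telomere path (Cd
and Cs shorten telomeres; shorter telomeres add years), covariate shifts,
and Gaussian noise (SD 3.5 years). OA is Bernoulli with log-odds 0.055
per year of mediator age (OR ≈ 1.06/year), small direct Cd/Co/Cs effects,
and a baseline giving ~11% prevalence. Survey weights are i.i.d. gamma,
independent of the outcome, so weighted and unweighted estimands coincide
for testing. Covariate marginals loosely match U.S. adult survey
composition (~51% female) without claiming fidelity.

Biomarker panels are generated by inverting the aging scores around the
latent mediator age: the Klemera–Doubal panel is linear in mediator age
with realistic slopes and residual SDs, and the phenotypic-age panel
draws eight biomarkers around population means and lets glucose close the
linear-predictor gap, plus noise. This makes parameter recovery
well-defined: the computed scores correlate > 0.8 with the latent truth,
and mediation through the computed scores is attenuated relative to the
latent structure exactly as measurement error predicts — biological age,
the noisier construction, shows the stronger attenuation. Passing tests
therefore demonstrate estimator correctness under a known generative
model, not NHANES fidelity: the generator has no survey strata or
oversampling, no qPCR telomere error structure, no age-dependent metal
exposure, and metals independent of covariates by default.

## Problem sizes and runtime

The test suite runs the pipeline at the sizes a reviewer can wait for:
correlation convergence at n = 20,000; WQS weight recovery over 20
replicate cohorts of n = 5,000 with 100 bootstraps; mediated-proportion
recovery at true proportions 0.1/0.3/0.5 over 20 replicates of
n = 10,000 with 500 draws; the full pipeline at n = 4,000–5,000. The
acceptance script's single full run (n = 5,000, 100 bootstraps, 1000
draws) completes in under a minute on one CPU.

## Known limitations

Cross-sectional mediation assumes the causal ordering it models;
sequential ignorability is untestable and no sensitivity analysis is
included. The WQS direction must be chosen a priori, and a misspecified
direction surfaces only as a warning on the final fit. Robust-SE weighted
fits understate design effects relative to full survey variance.
Nonlinear and interactive mixture response (the role of kernel-machine
sensitivity models elsewhere) is out of scope, as are DNA-methylation
clocks and other aging measures beyond the three implemented.
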