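---
title: "Modelling postnatal cardiac hypertrophy in preterm-born infants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling postnatal cardiac hypertrophy in preterm-born infants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiogrowth)
```

## The scientific problem

Infants born preterm transition to the high-resistance postnatal
circulation with an immature myocardium. Across the first three postnatal
months their ventricular mass — indexed to body surface area — increases
roughly twice as fast as in term-born infants, and the increase is steeper
the earlier the birth. `cardiogrowth` implements the full desk-scale
analysis of this phenomenon: echocardiographic derivations, fetal-to-
postnatal growth standards, a statistical shape model of the four-chamber
ventricular silhouette, and the cohort statistics layer — all driven by a
synthetic-cohort generator so that every stage is testable without patient
data.

## The synthetic cohort generator

The generator emulates a two-group neonatal cohort (121 preterm, 134 term)
with a fetal extension. Its default calibration (`default_calibration()`)
is fixed once and treated as the study condition:

* **Gestational age at delivery** (weeks): preterm $N(33.9, 2.2^2)$
  truncated below 37, term $N(39.4, 1.3^2)$ truncated at or above 37, so
  the groups are disjoint at the clinical cut.
* **Echo measures at birth and 3 months**: truncated normals (two-sided at
  mean ± 4 SD, floored at physiologic minima) with the group means and SDs
  of the emulated cohort's summary tables — e.g. LV mass index
  18.8 (3.9) g/m² preterm vs 20.7 (3.9) term at birth. Raw chamber values
  are the indices multiplied by the Boyd BSA of the sampled weight, so the
  derivation layer recovers the configured indices exactly.
* **Percent mass-index change** from birth to 3 months follows
  $\Delta\% = \alpha + \beta\,GA + \varepsilon$,
  $\varepsilon \sim N(0, \sigma_\varepsilon^2)$. `solve_ga_effect()`
  identifies $(\alpha, \beta, \sigma_\varepsilon)$ in closed form from the
  two target group means (57.8 % / 27.3 % for the LV, 39.3 % / 16.6 % for
  the RV), and from the target Pearson correlation between GA and
  $\Delta\%$ (−0.49 LV, −0.37 RV) via
  $r = \beta\sigma_{GA}/\sqrt{\beta^2\sigma_{GA}^2 + \sigma_\varepsilon^2}$
  with $\sigma_{GA}$ the mixture SD of GA. Because GA is *sampled
  truncated*, the solver is fed the analytic truncated-normal group
  moments (33.55/39.50 wk, SDs 1.90/1.20) rather than the raw parameters;
  with raw moments the realized group means would be biased by about 2 %,
  which is detectable at the 50,000-subject validation size. The follow-up
  mass index is the birth draw carried through the percent change, never
  an independent draw.
* **Within-group SDs of $\Delta\%$ are emergent**, not enforced: the
  implied preterm LV SD, $\sqrt{\beta^2\sigma_{GA,pre}^2 +
  \sigma_\varepsilon^2} \approx 32$ %, understates the reported 41.9 %.
  Matching the group means and the GA correlation exactly was preferred
  over matching all second moments, which the linear single-slope model
  cannot do simultaneously.
* **Head circumference** follows a logistic curve in postmenstrual age,
  $HC(t) = 44/(1 + e^{-0.10\,(t - 26.5)})$ cm, with a per-subject
  log-normal scale factor (SD 0.02). The anchor points reproduce the
  cohort's printed birth and 3-month HC means (30.7/34.5 and
  39.1/40.8 cm) and plausible fetal biometry; within a subject HC is
  strictly increasing, which is all the downstream analysis uses.
* **Fetal mass trajectory**: $\ln(\text{LV mass}) = b_0 + b_1\ln t + b_2 t$
  plus a subject random intercept (SD 0.15) and visit noise (SD 0.12),
  with coefficients interpolating 0.35 g at 20 weeks, the term birth mass
  (4.7 g) at 40 weeks and the term 3-month mass at about 53 weeks; the
  curve is monotone to past 70 weeks. Fetuses carry 1–5 scans with the
  observed repeat-visit profile (57/22/11/6/3 %).
* **Contours**: each postnatal visit carries an endocardial/epicardial
  border pair from the parametric family below, with per-group mean
  globularity +0.5 (preterm) vs −0.5 (term) at birth and 0 for both groups
  at follow-up — the birth-only shape contrast the analysis is designed to
  detect.

What the generator does *not* emulate: measurement dropout and missing
views, observer variability, correlation between echo measures beyond the
mass-change model, skewness of the raw measures, and any image-level
process. Passing tests therefore demonstrate that the analysis machinery
recovers known structure of this idealized data-generating process, not
that it would behave identically on real echocardiograms.

## Echocardiographic derivations

All derivations are deterministic and vectorised (`derive_measures()`):

* **Boyd BSA**, weight-only form
  $BSA = 0.0004688\,W^{\,0.8168 - 0.0154\log_{10}W}$ (W in g). The
  weight-only variant is used because it reproduces the emulated cohort's
  printed BSA means from its printed weights (2053 g → 0.16 m²,
  3315 g → 0.23 m², 4960 g → 0.30 m²) and infant length is unreliable.
* **Cube-formula LV mass** from linear measures:
  $0.8 \cdot 1.04[(IVSd + LVIDd + PWd)^3 - LVIDd^3] + 0.6$ g.
* **Single-plane area–length volume** $V = 8A^2/(3\pi L)$, and **shell
  mass** $1.05\,(V_{epi} - V_{endo})$ g with both volumes evaluated at the
  epicardial long-axis length (apex to annulus midpoint) and a myocardial
  density of 1.05 g/ml. Whether a disk-summation rule would serve equally
  is isolated behind `shell_mass_from_contours()`.
* Ejection fraction, stroke volume, mass/EDV, E/A, E/E′ and per-HC
  indexing follow their definitions; zero denominators propagate as
  missing values with a warning, never as errors.

## Growth centiles

`fit_fp_mean()` fits fractional polynomials of postmenstrual age to
$\ln y$ by exhaustive search over the conventional power set
$\{-2,-1,-0.5,0,0.5,1,2,3\}$ (8 degree-1 models, 36 degree-2 pairs with
repetition; power 0 is $\ln t$, a repeated power contributes
$t^p$ and $t^p\ln t$). The lowest residual sum of squares wins; ties break
toward the linear powers and then lexicographically, which only matters on
noise-free data. Degree 2 is the default — the flexibility is needed for
the fetal-to-postnatal mass span — with degree 1 available.

`fit_centile_model()` adds a log-scale SD model: constant by default
(log transformation is what stabilizes the variance), an age-varying
degree-1 fractional polynomial behind `sd_model = "fp"`. With
`repeated = TRUE` a subject random intercept is estimated by a
between/within moment decomposition and the mean curve refit by
quasi-demeaning GLS; full likelihood was deliberately avoided since with
these designs the hierarchical and flat fits are nearly identical (the
zero-variance case reduces exactly to OLS, which the tests assert).
Centiles are $\exp(\hat\mu(t) + z_p\hat\sigma(t))$; z-scores invert them.
Models refuse to extrapolate beyond the fitted age range unless
`extrapolate = TRUE`, because fractional polynomials are untrustworthy
outside support. Centile curves are nested by construction since
$\hat\sigma > 0$.

Two further choices the source analysis leaves open: whether preterm
trajectories are scored against the term standard (`zscore()`), or fit as
their own standard and compared pointwise (`trajectory_difference()`) —
both are supported and stage 3 of the workflow exercises both.

## Shape model

Correspondence is by arc-length resampling of each border (50 points by
default) anchored at the two annulus corners and the apex; the source
imaging pipeline's correspondence step is not described, and equal
arc-length spacing is the neutral choice for smooth open borders.

The contour family is a **superellipse arc**
$|x/(W/2)|^m + |y/L|^m = 1$, truncated at the annulus chord of width
$a W$, with the exponent and the length/width ratio linear in globularity
$g$: $m = 2 + 0.4g$, $L/W_{chord} = 1.55 - 0.35g$, so $g = +1$ is a
globular ventricle (ratio 1.2, $m = 2.4$) and $g = -1$ a conical one
(ratio 1.9, $m = 1.6$). The epicardial border is the outward normal offset
by the wall thickness. This family is an invented, documented stand-in for
traced borders: it reproduces the globular-vs-conical axis the analysis
targets while remaining analytically checkable (areas and arc lengths have
quadrature oracles).

Alignment is generalized Procrustes with **scale retained** (translation
and rotation only, proper rotations enforced), so that overall size
emerges as mode 1 of the PCA instead of being normalized away — the
analysis then *removes* mode 1 rather than pre-scaling, reproducing the
two-step size-then-shape narrative. Rotations use the closed-form 2-D
least-squares angle; convergence is declared when the mean shape moves
less than $10^{-8}$ (typically 2–4 iterations).

The morphological signature is a ridge-stabilized Fisher discriminant over
standardized mode scores,
$w = (S_{pooled} + \epsilon I)^{-1}(\mu_{pre} - \mu_{term})$ with
$\epsilon = 10^{-6}\,\mathrm{tr}(S)/d$ — whether raw or standardized
scores are combined does not change the AUC, since the discriminant is
equivariant to per-mode scaling. Nested subsets $\{2\}, \{2,3\}, \ldots$
are compared by leave-one-out AUC (Mann–Whitney rank statistic, ties
averaged) and the smallest subset within 0.005 of the maximum wins.
Numerical caveat, asserted in the tests: under the null the LOO
discriminant score is *pessimistically* biased (removing an observation
pushes its own group mean away from it), so single-permutation LOO AUCs
scatter widely below 0.5; chance-level behaviour is asserted on averages
over permutations.

## Cohort statistics

Welch's t-test is the default two-group comparison (the group variances
are visibly unequal), with Student's pooled test available by name.
Mann–Whitney uses exact enumeration of all group assignments up to pooled
n = 20 (ties via average ranks) and the tie-corrected normal approximation
above. The χ² association test is Pearson's without continuity correction
(Yates behind a flag). Forced-entry OLS reports unstandardized B with
normal-equation-checked coefficients and names collinear columns on rank
deficiency — mirroring the steroid/prematurity co-linearity handling,
where antenatal steroids must be excluded from multivariable models. No
multiple-testing correction is applied anywhere, matching the source
analysis convention. The minimal detectable effect uses the
normal-approximation closed form
$d = (z_{1-\alpha/2} + z_{power})\sqrt{1/n_1 + 1/n_2}$, giving 0.351 SD
at n = 134/121 — consistent with (slightly tighter than) the 0.38 SD the
study quotes; a noncentral-t variant is available and is marginally more
conservative.

## Problem sizes and numerical choices

The validation workloads were chosen as the smallest sizes at which each
statistical claim is decisively testable: calibration recovery uses
50,000 subjects per group (group-mean standard errors ≈ 0.15 %), centile
coverage uses 10,000 fresh points (binomial SE ≈ 0.2 %), the shape null
uniformity check uses 60 independent 15-vs-15 cohorts, and median-curve
recovery is asserted at 2 % on 4,000-point fits — at 1,000 points the
estimator's own edge sampling error (about 2–3 %) dominates, so only a
5 % band is claimed there. Truncated-normal sampling is inverse-CDF (no
rejection loops); degenerate noisy contours are regenerated from a
jittered seed at most 10 times before erroring; eigenvalues are clipped at
zero; the LDA ridge floor is $10^{-12}$ so point-mass classes remain
solvable.

## Known limitations

* The generator's independence assumptions (echo measures conditionally
  independent given group and stage; covariates independent except
  steroids) understate real-world correlation structure.
* The linear GA-effect model cannot reproduce the reported within-group
  SDs of percent change simultaneously with the means and correlation.
* The contour family is 2-D, convex, and noise-isotropic; real traced
  borders are none of these.
* Fractional-polynomial standards are only evaluated within the observed
  age support; the follow-up ages of the most preterm infants sit at the
  edge of the fetal-anchored standard where leverage is highest.
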