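---
title: "Modelling individual target-lesion kinetics: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling individual target-lesion kinetics: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesionkinetics)
```

## The scientific problem

Solid-tumour trials record each patient's RECIST *target lesions*
quantitatively — the longest diameter of each lesion at every imaging
visit — but routinely collapse them into a single per-patient sum (the
SLD) before analysis. That collapse discards the information this package
is built to extract: how much of the variability in treatment response and
in the emergence of resistant re-growth lives *between* patients versus
*between lesions within a patient*, and whether the speed at which a
lesion shrinks predicts the speed at which its resistant clone grows back.

## Structural model

A geometric argument motivates linearity in diameter: if proliferation is
confined to an outer rim of constant thickness $d$ whose cells divide at
rate $a = \log 2 / t_d$, the rim volume satisfies $\dot V_p = a V_p$ with
$V_p \approx 4\pi r^2 d$, and with a frozen necrotic core
($\dot V_c = 0$) the radius obeys $\dot r = a d$: linear radial growth,
hence cubic volume growth. `growth_law_params()`, `shell_volume()` and
`radius_trajectory()` implement this derivation; note that
$\dot V_p = a V_p$ is the premise and $\dot r = a d$ its consequence —
differentiating the composed shell volume along the trajectory gives
$a V_p \cdot (2d/r)$, not $a V_p$, which is exactly the thin-shell
approximation at work. Treatment-induced shrinkage is taken linear too
(clearance of dead cells), and resistance enters in the simplest possible
way: a second linear phase. One lesion's longest diameter is then

$$
L(t) = \mathrm{BSL} + d\,\min(t, sp) + g\,\max(t - sp, 0) + e,
$$

with baseline diameter $\mathrm{BSL}$, decay rate $d$ (mm/day), re-growth
rate $g$ (mm/day), switch point $sp$ (days) and residual error $e$. Two
deliberate choices:

* **Continuity at the switch.** The two-line form is parameterised so the
  phases meet at $sp$. Writing the second phase as an intercept plus
  $g\,t$ (the "literal" two-equation reading) implies a jump of size
  $g \cdot sp$ at the switch, which has no biological meaning here;
  `predict_diameter(..., form = "literal")` retains it for comparison
  only.
* **No sign constraints.** Decay may be positive and re-growth negative;
  such sign-anomalous lesions are a *finding* (reported by
  `decay_regrowth_correlation()`), not an error.

Negative structural predictions are permitted — clipping at 0 mm happens
only in the observation model (`observe_diameter()`), so the fitting
machinery stays linear-Gaussian given the baseline.

## Mixed-effects hierarchy

Lesion parameters vary at two levels. The baseline is log-normal,
$\mathrm{BSL}_{ij} = \exp(\beta_0 + b_{ij})$ with lesion-level
$b_{ij} \sim N(0, \sigma_b^2)$, guaranteeing positivity. The slopes
decompose additively, e.g.
$d_{ij} = d_{\mathrm{pop}} + p_i + l_{ij}$ with independent normal
patient- and lesion-level deviations, and similarly for $g$. All random
effects are mutually independent (diagonal covariance), a single residual
SD is shared by all observations, and the switch point is one population
value: letting it vary per lesion is not identifiable on a five-visit
imaging schedule, so it is instead *selected* over the midpoints of
consecutive on-treatment visits (`sp_candidates()`: days 63, 116, 179 on
the default schedule) by maximised log-likelihood (`select_sp()`), ties
going to the earliest candidate — the conservative clinical reading that
resistance starts sooner.

Two hierarchies are compared (`compare_hierarchies()`): `lesion_only`
(every lesion an independent unit) and `patient_lesion` (lesions nested in
patients, with patient-level slope deviations added). They are nested, so
the patient model can only raise the maximised log-likelihood; selection
follows the raw log-likelihood, with AIC reported alongside but not used,
and ML (not REML) is used throughout because fits with different fixed
structures are compared.

## Marginal likelihood: why nested adaptive quadrature

Conditional on the patient-level slope deviations and on $b_{ij}$, each
lesion is linear Gaussian, so its slope random effects integrate
analytically into a per-lesion covariance. What remains is a
one-dimensional non-Gaussian integral per lesion (over $b_{ij}$, which
enters the mean through an exponential) inside an at-most-two-dimensional
integral per patient. The compiled backend exploits exactly this
structure: an adaptive Gauss-Hermite rule (15 nodes; 11 during fitting)
per lesion, centred and scaled at the conditional mode found by
safeguarded Newton, nested in an adaptive product rule (9 nodes per
dimension; 5 during fitting) over the patient effects whose centring uses
the exact gradient and Hessian of the integrated log-density obtained from
the inner quadrature's moments of $\exp(b)$. Every node evaluation is
$O(1)$ thanks to per-lesion sufficient statistics, and the same pass
yields the analytic score of all nine parameters (the posterior
expectation of the complete-data score), so a 200-patient likelihood-plus-
gradient evaluation costs about ten milliseconds and the outer optimiser
needs no finite differences.

A first-order Laplace approximation was the natural default and remains
available (`method = "laplace"`, the single-node special case), but on
instances this sparse — two to five observations per lesion — its error is
of order $10^{-3}$ to $10^{-1}$ per unit, which measurably distorts
likelihood comparisons between switch points; the nested rule agrees with
a brute-force dense quadrature (`method = "ghq"`, pure R, written
independently as an oracle) to $10^{-7}$ at negligible extra cost, and is
therefore the default.

Optimisation runs `nlminb` with the analytic score in monotone stages
(each stage's result is accepted only if it improves, so the recorded
trace is non-decreasing; stage-to-stage relative tolerance $10^{-8}$, at
most 500 quasi-Newton iterations), followed by block-coordinate and
simplex polish of the fixed effects, a boundary pass that pins any
variance component drifting below $e^{-4}$ to the $e^{-12}$ floor and
keeps the pin only if the likelihood improves, and — when the baseline
variance is pinned, making the mean linear in
$(\exp\beta_0, d_{\mathrm{pop}}, g_{\mathrm{pop}})$ — an exact
generalised-least-squares solve of the fixed effects. The polish matters in two real situations: the
ferociously ill-conditioned ridge of noise-free data, and singular fits
where a component belongs at zero (reported as "no variability required",
threshold $e^{-10}$, mirroring the empirical finding that some arms need
no re-growth variability at all). Starting values are per-lesion ordinary
least squares on the piecewise basis plus moment estimates of the variance
components; given its start, the fit is deterministic.

Empirical-Bayes lesion parameters are the modal $b_{ij}$ (hence
$\widehat{\mathrm{BSL}} = \exp(\beta_0 + \hat b)$) and the conditional
means of the slope deviations at that mode. EB shrinkage attenuates
between-lesion scatter, so `decay_regrowth_correlation()` also offers raw
per-lesion least squares (`estimator = "ols"`) as an unshrunk alternative.

## The synthetic world

The original trial arms are not redistributable, so validation runs
against `simulate_cohort()`, whose defaults *are* the stated world rather
than tunable knobs:

| parameter | default | why |
|---|---|---|
| visits | days 0, 42, 84, 147, 210 | the trials' imaging schedule |
| lesions/patient | pmf on 1-7, zero at 6 | 80% of patients multi-lesion; observed counts skip six |
| baseline | lognormal(log 20, 0.40) | ILD median 20 mm, quartiles ≈ (15, 26) |
| decay | −0.17 ± 0.05 (patient) ± 0.05 (lesion) mm/day | week-6 median SLD change ≈ −34%, ORR ≈ 60% |
| re-growth | 0.07 ± 0.02 ± 0.02 mm/day | partial re-growth by day 210 |
| switch | day 63 | between the first two on-treatment visits |
| residual SD | 1.5 mm | realistic calliper/reader error |

Two calibration targets conflict under the model's own independence
assumption: a week-6 median SLD change near −35% and a clipped-observation
fraction below 1%. With baseline size and absolute decay rate independent,
any calibration deep enough for the former forces small lesions through
zero near the day-84 nadir; the defaults keep the realistic response depth
and accept a ~3% clipped fraction (logged as
`truth$clipped_fraction`). This is the one place the generator knowingly
violates its own fitting model — clipped zeros are real RECIST data
(disappeared lesions) but the Gaussian likelihood treats them as exact —
and it costs the decay estimate a small attenuation (about 3% at the
default world, inside the 5% recovery budget).

What a green recovery test does **not** establish: the generator draws
slopes independently of baseline size, has no reader-to-reader
variability, no new-lesion appearance, no death, and (by default) no
informative dropout — `dropout_at_pd = TRUE` adds trial-realistic
truncation after the first PD visit but is off so recovery experiments see
complete series. Real-arm conclusions inherit all those simplifications.

## Numerical choices and degenerate inputs

* RECIST 1.1 target-lesion thresholds (PR ≤ −30%, PD ≥ +20%, CR = all
  target diameters zero), referenced to baseline; at the first
  on-treatment visit — the only visit the inclusion filter uses —
  baseline and nadir coincide, so the distinction is moot there.
* Candidate switch points round half-up (115.5 → 116), matching the
  published candidate days; R's own half-even rounding would give 178
  instead of 179.
* Quantiles are type 7 (linear interpolation), pinned because published
  summary-table comparisons depend on the convention.
* CV = SD / |mean|; decay means are negative and the sign travels
  separately. A zero mean flags the entry rather than returning infinity.
* Zero-variance and zero-noise inputs are legitimate: the quadrature
  collapses to closed Gaussian forms when $\sigma_b = 0$, and the
  boundary polish recovers noise-free cohorts to optimiser precision.
* Measurements on unscheduled days are rejected, not snapped: midpoint
  candidate construction must stay well defined.

## Known limitations

The linear law holds for intermediate tumour sizes only (no Gompertz
saturation, no early exponential phase). The switch point is a population
approximation — per-lesion switch times are genuinely unidentifiable on
this schedule. Standard errors are not reported beyond what the
observed-information machinery of the backend would support; model
comparison is by likelihood, not hypothesis testing. The clipping bias
noted above grows if the generator is pushed to deeper responses or
smaller baselines than the defaults.
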