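---
title: "Joint population pharmacokinetics of voriconazole and its N-oxide: model, estimation and simulation methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint population pharmacokinetics of voriconazole and its N-oxide}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Voriconazole (VCZ) is a triazole antifungal with notoriously variable
exposure: it is cleared mainly by CYP2C19-mediated N-oxidation, the pathway
saturates at therapeutic concentrations, and the circulating metabolite
voriconazole N-oxide (VNO) itself inhibits the enzyme. Patients carrying
loss-of-function *CYP2C19* alleles (intermediate and poor metabolizers, IM
and PM) run substantially higher troughs than normal metabolizers (NM) on
the same dose. Therapeutic drug monitoring targets a trough window of
roughly 1–5.5 mg/L (2–5.5 mg/L for the stricter efficacy bound).

`voripk` implements a joint parent–metabolite population model for adult
patients on oral maintenance dosing with trough-based TDM sampling, plus
the machinery around it: mixed-effects estimation, model qualification,
and Monte Carlo dose-optimization simulation stratified by CYP2C19
phenotype.

## Structural model

One compartment for each analyte, first-order absorption, and mixed
linear/saturable parent elimination with metabolite auto-inhibition:

$$
\begin{aligned}
\frac{dA_\mathrm{gut}}{dt} &= -k_a A_\mathrm{gut}\\
\frac{dA_1}{dt} &= F k_a A_\mathrm{gut}
  - \frac{CL_1}{V_1} A_1 - \frac{CL_\mathrm{nonlin}}{V_1} A_1\\
\frac{dA_2}{dt} &= \frac{CL_\mathrm{nonlin}}{V_1} A_1 k_n
  - \frac{CL_2}{V_2} A_2\\
CL_\mathrm{nonlin} &= \frac{V_\mathrm{max}}{C_1 + K_m}
  \left(1 - \frac{I_\mathrm{max} C_2}{IC_{50} + C_2}\right),
\qquad C_1 = A_1/V_1,\; C_2 = A_2/V_2
\end{aligned}
$$

with amounts in mg, times in hours, concentrations in mg/L. $CL_1$ lumps
every parent elimination route other than N-oxidation; the model does not
distinguish renal from residual hepatic clearance because trough-only data
cannot. Two running states accumulate $\int C_1\,dt$ and $\int C_2\,dt$ so
that windowed AUCs are solver-accurate instead of trapezoidal.

Trough-only sampling cannot identify the absorption phase or the
saturation/inhibition constants, so $F = 0.895$, $k_a = 1.1\,h^{-1}$,
$K_m = 1.15$ mg/L, $I_\mathrm{max} = 0.75$ and $IC_{50} = 14.6$ mg/L are
fixed at literature values; $V_1$, $CL_1$, $V_2$, $V_\mathrm{max}$ and
$CL_2$ are estimated.

**The conversion factor `kn`.** The metabolite gain term needs a factor
converting parent mass cleared into metabolite mass gained. The package
defaults to $k_n = 1$ — the metabolite compartment is tracked in mg of
parent-drug equivalents, and every nonlinearly cleared parent molecule
enters it. The alternative reading (the VNO/VCZ molar-mass ratio, about
1.046) is available through the `kn` field of `fixed_effects()`. With
$k_n = 1$ the system obeys an exact mass balance,
$F(D_\mathrm{dosed} - A_\mathrm{gut}) = A_1 + A_2 + CL_1\!\int\!C_1 +
CL_2\!\int\!C_2$, which the test suite verifies to $10^{-6}$ relative over
two weeks of dosing.

## Statistical model

Inter-individual variability is lognormal, $P_i = \theta e^{\eta_i}$ with
$\eta_i \sim N(0, \omega^2)$, on $V_1$, $CL_1$, $CL_2$ and
$V_\mathrm{max}$ (diagonal $\Omega$; the study data give no support for
covariances). Residual error is proportional per analyte,
$C_{ij} = \hat C_{ij}(1 + \varepsilon_{ij})$; additive and combined forms
are also implemented. The CYP2C19 phenotype acts on $V_\mathrm{max}$
through the exponential categorical form
$V_{\mathrm{max},i} = V_\mathrm{max} e^{\theta_\mathrm{phen}}$ with NM as
reference; continuous covariates use the median-centred power form during
screening.

**Reading the variability table.** Published PopPK tables often report
$\omega$ terms as bare percentages without stating the transform. The
package makes the convention explicit in `omega_spec()` and supports three
readings: the value as $100\,\omega$ (`sd_times_100`), as a lognormal CV%
(`cv_percent`), and as $100\,\omega^2$, i.e. the variance as printed by
estimation software that reports omega-squared (`var_times_100`). The
default is `var_times_100`: it is the only reading under which the
reference estimates reproduce the published dose-simulation table (the
other two readings visibly under- or over-disperse the simulated trough
distribution), and it is consistent with software that prints the
estimated variance. Because this choice dominates the simulation results,
`scripts/acceptance.R` prints the anchor cells under all three
conventions.

## Estimation: FOCE-I with a compiled inner problem

The marginal likelihood of each subject's observations integrates over
$\eta_i$. The package approximates it the standard way: find the
conditional mode $\hat\eta_i$ of the joint density, then apply a Laplace
correction with a Gauss–Newton (first-order) approximation to the
conditional Hessian, $A_i = G_i^\top V_i^{-1} G_i + \Omega^{-1}$, where
$G_i$ is the sensitivity of the predictions to $\eta$ and $V_i$ the
residual variances evaluated at the mode (the "interaction" variant —
necessary here because proportional error makes $V_i$ depend on $\eta$).
The objective is
$$
\mathrm{OFV} = \sum_i \Big[ \sum_j \big(\log 2\pi v_{ij} +
r_{ij}^2/v_{ij}\big) + \log|\Omega| + \hat\eta_i^\top \Omega^{-1}\hat\eta_i
+ \log|A_i| - q \log 2\pi \Big]
$$
with all normalizing constants kept, so $\mathrm{AIC} = \mathrm{OFV} + 2p$
and $\mathrm{BIC} = \mathrm{OFV} + p\log n$ hold as identities and
likelihood-ratio differences are directly comparable across nested models.
For models whose predictions are linear in $\eta$ with additive Gaussian
error this expression is the exact marginal $-2\log L$; that is the
correctness oracle used by the tests (`laplace_ofv_ref()` is a slow,
pluggable-prediction R reference implementation kept independent of the
compiled path).

Numerical design of the inner problem (per subject, in C++):

* damped Gauss–Newton with a backtracking line search on the full
  conditional objective, including the $\partial \log v/\partial\eta$
  interaction term in the gradient — omitting it (a tempting shortcut)
  leaves the iteration stalling at non-stationary points;
* steps clamped to 2 log units per iteration (larger excursions make the
  ODE system arbitrarily stiff and are never accepted anyway);
* the Jacobian $G_i$ is frozen between refreshes because Gauss–Newton
  converges linearly here — recomputing it every iteration costs $2q$
  simulations for no faster convergence; it is refreshed when the mode has
  moved appreciably and re-evaluated for the final $\log|A_i|$ if the
  mode drifted since the last refresh;
* conditional modes are warm-started across outer iterations.

The outer problem maximizes over log-transformed positive parameters
(covariate effects untransformed) with `nlminb`, using an explicit
central-difference gradient with a step of $10^{-3}$ on the transformed
scale, restarted once from its own solution. Three details matter. First,
during optimization the ODE system is integrated on a *fixed* step grid
(0.5 h) rather than adaptively: an adaptive integrator's accept/reject
sequence changes discontinuously with the parameters, which puts kinks of
order $10^{-4}$ in the objective and destroys naive finite-difference
gradients. Second, the gradient step must sit well above the residual
noise floor left by finite inner-convergence tolerance (about $10^{-4}$
OFV units). Third, the differences must be central: the curvature of this
objective makes the $O(h\,f'')$ bias of one-sided differences large enough
to stall the optimizer several OFV units short of the optimum. Plain
evaluations (`eval_only`) use the adaptive Dormand–Prince 5(4) integrator
at rtol $10^{-8}$/atol $10^{-10}$.

Standard errors come from the numerical Hessian of the objective at the
optimum (delta method back to the natural scale). Trough-only designs with
fixed $F$ and $k_a$ leave $V_1$ weakly identified; the fitter reports an
ill-conditioning warning (condition number of the information matrix)
rather than failing. Observations below the assay quantification limit
(0.5 ng/ml) are excluded from the likelihood with a logged count.

## Covariate selection and qualification

`stepwise_covariates()` runs forward selection (ΔOFV > 3.84, $\chi^2_1$,
p ≤ 0.05) followed by backward elimination (ΔOFV ≥ 6.63, p ≤ 0.01), with a
pre-screen (`collinearity_screen()`, rank-based correlation, |r| > 0.5
flags mutually exclusive pairs — body weight and BSA being the canonical
example). Every tested step lands in a trace table; failed candidate fits
are recorded and skipped, never silently dropped.

Qualification mirrors standard practice: `pk_bootstrap()` resamples
subjects with replacement and reports medians, 95% percentile intervals
and the relative bias (bootstrap median vs original estimate);
`vpc()` simulates replicates of the observed design and overlays observed
2.5/50/97.5 percentiles on the simulation confidence bands, binned by
time-after-dose quantiles (the study's sampling is trough-clustered, so
equal-count bins beat equal-width ones; a prediction-corrected variant is
available); `cwres()` computes conditional weighted residuals from the
FOCE linearization, collapsing to $(y-\hat y)/\sigma$ in the
no-random-effects limit.

## Dose-optimization simulation

`pta_table()` simulates, per phenotype × regimen cell, `n_subjects`
individuals with inter-individual variability only — residual error is
measurement noise, not biology, so target-attainment decisions use
residual-free predictions — integrates 14 days of maintenance dosing, and
summarizes the day-14 pre-dose trough: its median and the percentage at or
above 1, 2 and 5.5 mg/L. Steady state is verified by comparing the last
two dosing intervals (relative change < 0.5%); subjects still drifting are
re-checked over a doubled horizon and counted in `n_unconverged`, but the
*reported* trough remains the day-14 value — that is the quantity the
reference table is defined on, and with $\omega_{V_1}$ this large a small
tail of extreme-volume subjects never converges in any practical horizon.
Maintenance-only dosing is used for steady-state tables (loading doses do
not change steady state); `standard_regimen_profile()` reproduces the
20-day course under the labelled regimen (400 mg BID × 2 then 200 mg BID)
with a 10–90% prediction band. The Monte Carlo standard error of each
attainment percentage is reported alongside each cell.

## The study emulator

`generate_cohort()` forward-simulates the TDM design the model targets: 78
subjects (27 NM / 32 IM / 16 PM / 3 ungenotyped), 200 mg q12h with no
loading dose, trough-only samples (1–8 occasions, mean ≈ 2.74, so the
expected observation count matches the study's 427 dual-analyte records;
one metabolite record is dropped to mirror the 214/213 imbalance). First
sampling occasions are log-uniform over 23–4223 h after the first dose —
the study reports only the range, and TDM visit times are
multiplicative-scale quantities — and each trough falls in the final half
hour before a dose. Covariates are drawn from truncated normal
(anthropometrics) or lognormal (right-skewed laboratory values)
distributions matched to the published summaries; they are generated
independently except BSA, which is computed from height and weight by the
Mosteller formula. This is a deliberate simplification — only marginal
summaries are published — and it means the generator reproduces marginal,
not joint, covariate structure. Ungenotyped subjects are simulated with NM
kinetics but labelled `UNK`, exercising the estimation side's
reference-category imputation. Laboratory covariates are causally inert in
the generator, preserving the negative-control surface for covariate
screening.

`generate_rich_cohort()` is the identifiability-friendly companion used by
the recovery suite: seven days of q12h dosing, samples on the first dosing
day and densely across a steady-state interval, phenotypes cycling
NM/IM/PM.

What passing tests on these cohorts do **not** show: robustness to
real-data features the emulator omits — dose adjustments mid-therapy,
dropout, comedication interactions, correlated covariates, assay batch
effects, or model misspecification of the absorption phase.

## Problem sizes used by the test suite

The suite's simulation-based checks use sizes chosen to make each claim
statistically meaningful while keeping a full run comfortably fast:
parameter recovery uses 10 replicate rich cohorts of n = 100, scored by
the median estimate across replicates against the generating value (the
usual simulation–estimation bias summary — per-replicate scatter of the
CYP2C19 effects is information-limited: their standard error at this
design is about ω_Vmax·√(2/33) ≈ 0.11, a third of the IM effect itself);
recovery fits start from displaced initial values — structural parameters
off by 15%, covariate effects shrunk 30% toward zero, inflated
variability terms; the null-calibration of stepwise selection uses 12
replicates of n = 30 (the χ² calibration of ΔOFV is essentially
sample-size free); attainment anchors use 1000 subjects per cell in tests
and 20 000 in `scripts/acceptance.R` (Monte Carlo SE ≈ 0.3 percentage
points); bootstrap machinery is exercised on cloned-subject cohorts where
the correct answer (zero-width intervals) is exact. The reference
analysis's own bootstrap scale (1000 resamples) and VPC scale (1000
replicates) are the defaults of the corresponding functions.

## Known limitations

* Absorption parameters are fixed, so any misfit in the absorption phase
  is invisible by construction.
* The FOCE objective here is an approximation; it is exact only in the
  linear-Gaussian limit the oracles test. Agreement with other FOCE
  implementations is expected at the level of the statistical
  approximation, not to the last decimal of a proprietary objective.
* With $\omega_{V_1}$ of the magnitude the reference analysis reports,
  individual volume spans two orders of magnitude; the simulated trough
  distribution is then sensitive to how the variability table is read
  (see `omega_spec()`), and reports should always state the convention.
* Below-quantification data are excluded rather than treated with a
  censored-likelihood method; at the study's LLOQ (0.0005 mg/L) this is
  immaterial, but the policy would matter for sparser, lower-dose designs.
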