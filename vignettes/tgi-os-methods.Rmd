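---
title: "Tumor growth inhibition and overall survival: model, estimation, and trial simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor growth inhibition and overall survival: model, estimation, and trial simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgios)
```

## The two-stage TGI-OS framework

`tgios` implements a two-stage link between longitudinal tumor burden and
overall survival (OS) of the kind used to support early decisions in
oncology drug development:

1. **Stage 1 — tumor dynamics.** The sum of longest diameters (SLD, mm) of a
   patient's target lesions is described by a biexponential tumor growth
   inhibition (TGI) model and fitted to all patients jointly as a nonlinear
   mixed-effects model. The empirical Bayes estimate (EBE) of each patient's
   tumor growth rate constant KG is extracted.
2. **Stage 2 — survival.** log(KG) and baseline prognostic factors enter a
   log-normal accelerated failure time (AFT) model for OS in days. The
   fitted model then drives a replicate virtual-trial simulator that
   produces OS distributions, landmark survival rates, and hazard ratios
   (HR) with 95% prediction intervals (PI).

The package is organized as an analysis workflow: the numbered scripts
under `analysis/` are thin narrative drivers (generate, fit TGI, fit OS,
simulate); every computation they perform lives in the package functions,
which is also what the test suite and `scripts/acceptance.R` exercise.
Because individual patient data from the emulated study design are not
publicly available, a synthetic-trial generator is a first-class module:
it defines the study conditions under which every pipeline stage is tested.

## Stage 1: the biexponential TGI model

For time $t$ in weeks relative to treatment start,

$$
TS(t) = \begin{cases}
TS_0\, e^{K_G t} & t < 0\\[2pt]
TS_0\left[e^{-K_S t} + e^{K_G t} - 1\right] & t \ge 0
\end{cases}
$$

with $TS_0$ the tumor size at treatment start (mm), $K_G$ the growth rate
constant and $K_S$ the shrinkage rate constant (week$^{-1}$). Both branches
equal $TS_0$ at $t = 0$; for $K_S > K_G$ the on-treatment curve decreases to
a nadir at $t^\* = \log(K_S/K_G)/(K_S+K_G)$ and regrows afterwards.
Screening scans at $t<0$ use the pre-treatment branch; whether they enter
the fit is a configuration flag (`tgi_control(include_prebaseline=)`,
default `TRUE`).

**Population model.** $K_G$ and $K_S$ have arm-specific typical values with
log-normal inter-individual variability (IIV); $TS_0$ has one typical value
and a common log-normal IIV; residual error is additive normal
($\sigma^2$, mm$^2$). The IIV covariance is diagonal — only variances are
identified in the reference estimates we reproduce, so eta correlations are
fixed at zero by design. IIV is reported as $CV\% = 100\sqrt{\omega^2}$
(`cv_percent()`), the convention under which the reference variance/CV
pairs are mutually consistent.

**Estimation.** The marginal likelihood is the Laplace approximation over
the per-subject random effects, with all parameters estimated on the log
scale for positivity. The joint model is written as a TMB C++ template
(`src/tgios.cpp`); TMB supplies exact automatic derivatives of the Laplace
objective, which `nlminb` maximizes. Standard errors come from the inverse
observed information (`TMB::sdreport`); RSE% is the natural-scale relative
standard error. EBEs are the inner posterior modes, and eta shrinkage is
$100(1 - SD(\eta_{EBE})/\sqrt{\omega^2})$.

**Numerical choices worth knowing.**

- *Spurious basins.* With additive error and log-scale parameters, a
  subject whose SLD series is short and non-monotone (e.g. a sharp drop,
  rebound, then plateau) can have a joint random-effect Hessian that turns
  singular at the mode. Because the Laplace objective contains
  $+\tfrac12\log|H|$, such points masquerade as likelihood gains and
  attract the optimizer; the gradient there is garbage and the covariance
  step fails. `fit_tgi()` defends against this in three ways: data-driven
  starting values (per-subject log-linear slopes pooled by arm), up to six
  jittered restarts (`n_starts`, `jitter_sd`), and a candidate ranking that
  prefers optima where the optimizer converged *and* the observed
  information is positive definite on both the estimation and reporting
  scales — over optima with nominally better objectives where it is not.
  If no start passes, the best candidate is returned with a warning and
  `NaN` standard errors rather than silently trusted.
- *Overflow guard.* The growth exponent $K_G t$ is continued linearly above
  30 inside the template; the cap is far outside any region supported by
  tumor-size data and only prevents overflow during optimizer excursions.
- *Convergence.* Outer relative tolerance $10^{-8}$, iteration cap 500;
  a warm restart of `nlminb` clears spurious "false convergence" stops.

**Oracle checks.** `tgi_marginal_loglik()` evaluates the Laplace marginal
log-likelihood at fixed parameters. The test suite compares it against an
independent adaptive Gauss–Hermite quadrature (mode and curvature found
with `optim`/`optimHess` on a separately written joint density, 25-node
product grid). The tight (≤ $10^{-3}$) agreement check runs at small IIV
($\omega^2 = 0.0025$), where the random-effect posterior is near-Gaussian:
there the Laplace *approximation error* is negligible and the check
isolates the *implementation* (mode finding, determinant bookkeeping,
constants). At moderate IIV ($\omega^2 \approx 0.1$) the approximation
itself drifts by $O(10^{-2})$ per subject — a property of Laplace, not a
bug — and the suite asserts only a loose bound there. At the realistic
$\omega^2 \approx 1\!-\!2$ no sub-$10^{-3}$ agreement should be expected.

## Stage 2: the log-normal AFT model for OS

$\log(\text{OS in days}) \sim N(\mu, \text{scale}^2)$ with

$$\mu = \beta_0 + \beta_{KG}\log K_G + \textstyle\sum_k \beta_k x_k,$$

where $\log K_G$ is the natural log of the EBE in week$^{-1}$ (natural log
is the pharmacometric convention and gives location magnitudes consistent
with the reference intercept), and the $x_k$ are albumin (g/L),
ECOG $\ge 1$ vs 0, Asian vs non-Asian, number of metastatic sites capped at
5 (`cap_met_sites()`), neutrophil-to-lymphocyte ratio, liver metastasis
yes/no, baseline SLD (mm), line of therapy 2+ vs 1, and female vs male.
Covariates enter in natural units, unstandardized (the reference table's
units are natural units). `survival_function()` gives
$S(t) = 1-\Phi((\log t - \mu)/\text{scale})$.

`fit_os()` maximizes the censored log-likelihood (density terms for
deaths, $\log S$ for censored times) with an analytic gradient, BFGS plus
an `nlminb` polish, and reports SEs from the inverse observed information
with Wald $z$ and two-sided $p$ values. `survival::survreg` is the
independent cross-check in the tests, never the implementation. Covariate
selection (`select_covariates()`) is backward elimination on Wald $p$ at
$\alpha = 0.01$; the reference publication does not describe its exact
add/drop procedure, so backward elimination is our documented stand-in,
and `log_kg` — the framework's core metric — is never dropped.

## Replicate virtual trials

`run_simulation()` repeats, per replicate: draw one coefficient vector from
estimation uncertainty; compute each subject's $\mu$ from their baseline
covariates and individual log KG; draw death times
$T \sim \text{LogNormal}(\mu, \text{scale})$ and censoring times
$C \sim \text{Uniform}(\text{censor bounds})$; summarize the replicate by
per-arm Kaplan–Meier curves on a monthly grid to 60 months, landmark rates
(default 2 years), and the Cox HR (Efron ties) of treatment vs control.
Replicate summaries are aggregated to medians and 2.5/97.5 percentiles.
The HR percentile across replicates is our documented reading of the
"prediction interval"; replicates with no events in an arm are excluded
from the HR percentiles and counted, never silently dropped.

Parameter uncertainty modes: `"diagonal"` (independent normal draws per
coefficient — the default, since published tables carry SEs but no
covariance), `"none"`, and `"full"` (multivariate normal from a fitted
model's covariance). When the OS model has just been refitted — as in
`analysis/04_simulate_trials.R` and `scripts/acceptance.R` — `"full"` is
used: with correlated regressors (intercept vs albumin, for instance),
independent draws ignore strong negative coefficient correlations and
visibly overstate the prediction intervals.

"Uniform censoring based on observed censoring" is implemented as
`Uniform(low, high)` with bounds taken from the observed censoring range of
the study being emulated (configurable; the reference gives no further
detail, and whether bounds should be arm-specific is unstated — we use one
global pair).

## The synthetic trial generator

`generate_trial()` emulates a two-arm first-line ALK-positive NSCLC design:
143 evaluable subjects per arm plus 17 baseline-only subjects (303
randomized, 286 evaluable), tumor assessments at baseline and every 8 weeks
up to 260 weeks, OS generated from the AFT truth driven by each subject's
*true* log KG, and uniform censoring between 1 and 5 years (about 60%
censored, matching the immaturity of OS data in such populations). The
default generating values are the published TGI estimates
(`default_tgi_truth()`: e.g. KG 0.00196 vs 0.00438 week$^{-1}$,
$\omega^2_{KG}$ 1.90/1.10, $\sigma^2$ 42.5 mm$^2$) and the published AFT
coefficients (`default_os_truth()`).

Covariate distributions are configuration, not claims about any real
population (`covariate_config()`): albumin $N(40, 4^2)$ g/L truncated above
20, P(ECOG ≥ 1) = 0.6, P(Asian) = 0.45, metastatic sites $1+$Poisson(1.5),
NLR LogNormal($\log 3.5$, $0.5^2$), P(liver met) = 0.2, P(2nd+ line) = 0
(first-line study), P(female) = 0.55; baseline SLD is the subject's
generated $TS_0$.

Dropout: the SLD series stops at the earliest of death, maximum follow-up,
and a progression proxy — the first visit where the *latent* (noise-free)
curve exceeds $1.2\times$nadir$+5$ mm. The proxy is applied to the latent
curve because real progression calls require radiological confirmation
that a single noisy reading would not trigger; applying it to the noisy
observations truncates series on measurement error alone and shortens
follow-up unrealistically. Under the defaults the median tumor-assessment
follow-up is ≈ 90–100 weeks. What the generator does *not* emulate: new
lesions as a progression trigger, the real joint covariate distribution,
CNS-metastasis stratification, crossover, and accrual patterns — so
passing recovery tests demonstrate estimator correctness under the stated
design, not performance on real trial data.

Two deliberate asymmetries connect the stages. The generator uses *true*
individual KG for OS; the pipeline uses EBEs. Shrinkage-induced
measurement error therefore attenuates refitted covariate effects and
inflates the refitted scale at $n \approx 286$ — visible in
`analysis/03_fit_os.R`, where only `log_kg` survives elimination at
$\alpha = 0.01$ with 113 events; the reference model's small covariate
effects were estimated on a training set an order of magnitude larger.
This is surfaced, not hidden, and the recovery tests that target the
published coefficients use the true log KG at $n = 2000$ instead.

## Problem sizes and tolerances used by the checks

- **TGI recovery**: 286 evaluable subjects (143/arm), default schedule,
  five seeds; seed-averaged typical values within ±20%, treatment-arm
  $\omega^2_{KG}$ within ±30% (the single-fit sampling SD of a typical
  value is ~10–15%, cf. reference RSEs of 4–17%). About 15–60 s per fit.
- **OS recovery**: $n = 2000$, censoring bounds (700, 4000) days chosen by
  solving $E[P(T>C)] \approx 0.40$ numerically before any testing; key
  coefficients within ±3 fitted SEs. Line of therapy is given
  P(2+) = 0.25 here so all ten covariates have variation.
- **Oracles**: adaptive Gauss–Hermite (≤ 3 subjects, ≤ $10^{-3}$), hand
  Kaplan–Meier products, brute-force Cox partial likelihood, term-by-term
  AFT likelihood sums.
- **Simulation**: 1000 replicates of a 286-subject trial in ~10 s; with
  arm-specific KG distributions and all else equal, the HR PI upper bound
  falls below 1.

## Known limitations

- The Laplace approximation degrades for subjects with very few
  observations and large IIV; the safeguards above make failures loud
  (warnings, `NaN` SEs) rather than impossible.
- The AFT scale refitted from EBEs is biased upward relative to the
  generating value (measurement error in log KG); a formal
  errors-in-variables treatment is out of scope.
- The progression proxy is an artifact choice; real RECIST progression
  (confirmation, new lesions) is richer.
- `km_estimate()`/`cox_hr()` wrap `survival`; they are plumbing for the
  simulator, with hand-computed oracles in the tests, not contributions.
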