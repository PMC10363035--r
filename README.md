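# tgios — tumor growth inhibition to overall survival modeling

`tgios` is an R implementation of the two-stage TGI-OS framework used in
oncology pharmacometrics to translate early longitudinal tumor-size data
into predictions of overall survival (OS) and treatment effect. It is aimed
at pharmacometricians and biostatisticians who want a tested, scriptable
version of the workflow: fit tumor dynamics, link the individual growth
rate to survival, and simulate replicate trials to get prediction intervals
on the hazard ratio — without NONMEM.

## The models

**Stage 1 — biexponential tumor growth inhibition.** The sum of longest
diameters TS(t) (mm, RECIST target lesions), with t in weeks from
treatment start:

```
TS(t) = TS0 * exp(KG * t)                          t < 0
TS(t) = TS0 * [exp(-KS * t) + exp(KG * t) - 1]     t >= 0
```

KG (growth) and KS (shrinkage, both week⁻¹) have arm-specific typical
values and log-normal inter-individual variability; TS0 has a common
log-normal distribution; residual error is additive normal. The population
model is estimated by Laplace-approximated maximum likelihood (a TMB
template with exact automatic derivatives), yielding typical values with
RSEs, variances ω² (reported as CV% = 100·√ω²), empirical Bayes estimates
(EBEs) per subject, and η-shrinkage.

**Stage 2 — log-normal accelerated failure time model for OS.**
log(OS days) ~ Normal(μ, scale²) with

```
μ = β0 + β_KG·log(KG) + β_alb·albumin + β_ecog·1[ECOG≥1] + β_race·1[Asian]
    + β_met·min(sites,5) + β_nlr·NLR + β_liv·1[liver met]
    + β_sld·baselineSLD + β_line·1[line 2+] + β_sex·1[female]
```

fitted by censored maximum likelihood with Wald inference, where log(KG)
is the natural log of the stage-1 EBE. A replicate simulator then draws
model coefficients from their estimation uncertainty, simulates per-patient
death and uniform censoring times, and aggregates Kaplan–Meier curves,
landmark survival rates, and Cox hazard ratios into medians with 95%
prediction intervals.

A synthetic-trial generator (`generate_trial()`) emulates a two-arm
ALK-positive first-line NSCLC design (303 randomized, 286 TGI-evaluable,
q8w assessments, ~5 years follow-up) with published TGI and OS estimates as
generating truths, so the whole pipeline runs and is tested without any
patient-level data.

## Worked example

```r
library(tgios)

vt  <- generate_trial(generator_config(n_per_arm = 40, n_baseline_only = 4, seed = 91))
fe  <- filter_evaluable(vt$data)      # keeps baseline + >=1 post-baseline
fit <- fit_tgi(fe$data)
fit
#> <tgi_fit> biexponential TGI population model (Laplace NLME)
#>   80 subjects, 1298 observations, logLik -4634.09
#>              estimate rse_pct omega2 iiv_cv_pct shrinkage_pct
#> kg_treatment  0.00168   22.60  1.600      127.0          8.91
#> ks_treatment  0.03270   16.80  0.843       91.8          9.65
#> kg_control    0.00387   14.70  0.761       87.2          2.61
#> ks_control    0.03650   14.40  0.732       85.6          8.71
#> ts0          60.80000    7.17  0.397       63.0          3.57
#>   sigma2 (residual variance): 35.7 mm^2
```

The treatment arm grows at 0.00168/week against 0.00387/week for control
(truths 0.00196 and 0.00438), with low KG shrinkage — the individual
estimates carry real information and can drive the survival stage:

```r
design <- os_design(fe$data$covariates, setNames(fit$ebes$log_kg, fit$ebes$subject_id))
os     <- fe$data$os[match(design$subject_id, fe$data$os$subject_id), ]
m      <- fit_os(os$os_days, os$event, design,
                 terms = c("log_kg", "albumin", "ecog_ge1", "n_met_sites"))
m
#> <os_model> log-normal AFT for overall survival (days)
#>   n = 80 (28 events), logLik -230.43, scale 0.9734
#>         term estimate     se     z       p
#>  (Intercept)   4.4100 1.4100  3.13 1.8e-03
#>       log_kg  -0.6430 0.1490 -4.33 1.5e-05
#>      albumin  -0.0108 0.0292 -0.37 7.1e-01
#>     ecog_ge1  -0.1880 0.2900 -0.65 5.2e-01
#>  n_met_sites  -0.1510 0.1290 -1.16 2.4e-01
#>    log_scale  -0.0270 0.1430 -0.19 8.5e-01
```

A faster-growing tumor shortens survival (β_logKG = −0.64, p = 1.5e-05);
at this small n the weaker prognostic effects are not resolvable. Simulating
500 replicate trials from the fitted model's full coefficient covariance:

```r
subjects <- cbind(arm = fit$ebes$arm[match(design$subject_id, fit$ebes$subject_id)], design)
run_simulation(m, subjects, sim_config(n_replicates = 500, seed = 1, uncertainty = "full"))
#> <sim_summary> 500 replicate virtual trials
#>   HR treatment vs control: 0.578 (95% PI 0.295-0.998)
#>   landmark survival (%):
#>        arm time_days median   lo   hi
#>  treatment       730   78.4 63.8 90.8
#>    control       730   64.6 48.5 80.7
```

The slower growth in the treatment arm translates into a predicted hazard
ratio below 1 and a ~14-point difference in 2-year survival.

## Analysis workflow

The `analysis/` scripts run the same pipeline at full study scale and write
their tables under `results/`:

```sh
Rscript analysis/01_generate_trial.R    # 303-subject synthetic trial
Rscript analysis/02_fit_tgi.R           # evaluability filter + population fit + EBEs
Rscript analysis/03_fit_os.R            # AFT fit on EBE log(KG) + covariates
Rscript analysis/04_simulate_trials.R   # 1000-replicate OS/HR prediction
```

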