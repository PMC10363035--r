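#' Published TGI population estimates used as default simulation truths
#'
#' Typical values, log-scale variances, and residual variance of the
#' biexponential TGI model for an ALK-positive first-line NSCLC study
#' (treatment arm vs an active-comparator control arm). These are
#' the generator's default generating values and the recovery targets of the
#' test suite.
#'
#' @return list with `theta` (week^-1, mm), `omega2`, `sigma2` (mm^2).
#' @export
default_tgi_truth <- function() {
  list(
    theta = c(kg_treatment = 0.00196, ks_treatment = 0.0342,
              kg_control = 0.00438, ks_control = 0.0373, ts0 = 57.0),
    omega2 = c(kg_treatment = 1.90, ks_treatment = 0.943,
               kg_control = 1.10, ks_control = 0.833, ts0 = 0.436),
    sigma2 = 42.5
  )
}

#' Published TGI-OS coefficient table used as default simulation truth
#'
#' Log-normal AFT coefficients (log-day scale) linking log(KG) and baseline
#' prognostic factors to overall survival, with their standard errors, as an
#' [os_model_from_table()] model. Survival time is in days; `log_kg` is the
#' natural log of KG in week^-1.
#'
#' @return an `os_model`.
#' @export
default_os_truth <- function() {
  os_model_from_table(data.frame(
    term = c("(Intercept)", "log_kg", "albumin", "ecog_ge1", "race_asian",
             "n_met_sites", "nlr", "liver_met", "baseline_sld", "line_2plus",
             "sex_female", "log_scale"),
    estimate = c(2.87, -0.642, 0.0262, -0.270, 0.319, -0.0733, -0.0138,
                 -0.174, -0.00122, -0.103, 0.0840, -0.225),
    se = c(0.164, 0.0224, 0.00274, 0.0295, 0.0433, 0.0147, 0.00263,
           0.0396, 0.000318, 0.0346, 0.0300, 0.0155),
    stringsAsFactors = FALSE
  ))
}

#' Baseline covariate samplers for the synthetic trial
#'
#' Marginal distributions emulating a first-line ALK-positive NSCLC
#' population. These are configuration, not estimates from any study:
#' albumin Normal(40, 4^2) g/L truncated above 20; P(ECOG >= 1) = 0.6;
#' P(Asian) = 0.45; metastatic sites 1 + Poisson(1.5); NLR
#' LogNormal(log 3.5, 0.5^2); P(liver metastasis) = 0.2; P(line 2+) = 0
#' (first-line study); P(female) = 0.55. Baseline SLD is taken from each
#' subject's generated `ts0`, so it is configured through the TGI truth.
#'
#' @param albumin_mean,albumin_sd,albumin_min albumin sampler (g/L).
#' @param p_ecog1,p_asian,p_liver,p_line2,p_female Bernoulli probabilities.
#' @param met_rate Poisson rate of extra metastatic sites beyond the first.
#' @param nlr_meanlog,nlr_sdlog log-normal NLR parameters.
#' @return list of class `covariate_config`.
#' @export
covariate_config <- function(albumin_mean = 40, albumin_sd = 4, albumin_min = 20,
                             p_ecog1 = 0.6, p_asian = 0.45, met_rate = 1.5,
                             nlr_meanlog = log(3.5), nlr_sdlog = 0.5,
                             p_liver = 0.2, p_line2 = 0, p_female = 0.55) {
  structure(as.list(environment()), class = "covariate_config")
}

#' Sample baseline covariates
#'
#' Draws `n` subjects' baseline covariates from a [covariate_config()].
#' `baseline_sld` is left `NA`; the trial generator fills it from each
#' subject's generated tumor size at treatment start.
#'
#' @param n number of subjects.
#' @param cfg a [covariate_config()].
#' @param ids subject identifiers (default "S001"...).
#' @return covariate data.frame in the [trial_dataset()] schema.
#' @export
sample_covariates <- function(n, cfg = covariate_config(), ids = NULL) {
  stopifnot(inherits(cfg, "covariate_config"))
  if (is.null(ids)) ids <- sprintf("S%03d", seq_len(n))
  # truncated normal by rejection; truncation point is far in the tail
  alb <- rnorm(n, cfg$albumin_mean, cfg$albumin_sd)
  while (any(bad <- alb <= cfg$albumin_min)) {
    alb[bad] <- rnorm(sum(bad), cfg$albumin_mean, cfg$albumin_sd)
  }
  data.frame(
    subject_id = ids,
    albumin = alb,
    ecog = rbinom(n, 1, cfg$p_ecog1),
    race = ifelse(rbinom(n, 1, cfg$p_asian) == 1, "Asian", "non-Asian"),
    n_met_sites = 1L + rpois(n, cfg$met_rate),
    nlr = rlnorm(n, cfg$nlr_meanlog, cfg$nlr_sdlog),
    liver_met = ifelse(rbinom(n, 1, cfg$p_liver) == 1, "yes", "no"),
    baseline_sld = NA_real_,
    line_of_therapy = ifelse(rbinom(n, 1, cfg$p_line2) == 1, "2+", "1"),
    sex = ifelse(rbinom(n, 1, cfg$p_female) == 1, "female", "male"),
    stringsAsFactors = FALSE
  )
}

#' Draw individual TGI parameters from the population distribution
#'
#' Per-subject `(ts0, kg, ks)` drawn log-normally around the arm-specific
#' typical values with the configured log-scale variances.
#'
#' @param arm character vector ("treatment"/"control"), one per subject.
#' @param truth a [default_tgi_truth()]-shaped list.
#' @return data.frame with `ts0`, `kg`, `ks`, `log_kg` and the drawn etas.
#' @export
sample_tgi_params <- function(arm, truth = default_tgi_truth()) {
  n <- length(arm)
  trt <- arm == "treatment"
  kg_t <- ifelse(trt, truth$theta[["kg_treatment"]], truth$theta[["kg_control"]])
  ks_t <- ifelse(trt, truth$theta[["ks_treatment"]], truth$theta[["ks_control"]])
  w_kg <- ifelse(trt, truth$omega2[["kg_treatment"]], truth$omega2[["kg_control"]])
  w_ks <- ifelse(trt, truth$omega2[["ks_treatment"]], truth$omega2[["ks_control"]])
  eta_kg <- rnorm(n, 0, sqrt(w_kg))
  eta_ks <- rnorm(n, 0, sqrt(w_ks))
  eta_ts0 <- rnorm(n, 0, sqrt(truth$omega2[["ts0"]]))
  out <- data.frame(
    ts0 = truth$theta[["ts0"]] * exp(eta_ts0),
    kg = kg_t * exp(eta_kg),
    ks = ks_t * exp(eta_ks),
    eta_kg = eta_kg, eta_ks = eta_ks, eta_ts0 = eta_ts0
  )
  out$log_kg <- log(out$kg)
  out
}

#' Simulate overall-survival outcomes from the AFT truth
#'
#' Death times are log-normal with location from [linear_predictor()] under
#' `os_truth` (using the subjects' *true* individual log KG) and the model
#' scale; censoring is a uniform study duration.
#'
#' @param design design data.frame from [os_design()].
#' @param os_truth an `os_model` used as generating truth.
#' @param censor_bounds length-2 days for Uniform censoring.
#' @return list: `os` (subject_id, os_days, event), `mu`, `death_days`,
#'   `censor_days`.
#' @export
generate_os <- function(design, os_truth = default_os_truth(),
                        censor_bounds = c(365, 1825)) {
  mu <- linear_predictor(os_truth, design)
  death <- rlnorm(length(mu), mu, os_truth$scale)
  cens <- runif(length(mu), censor_bounds[1], censor_bounds[2])
  list(
    os = data.frame(subject_id = design$subject_id,
                    os_days = pmin(death, cens),
                    event = as.integer(death <= cens),
                    stringsAsFactors = FALSE),
    mu = mu, death_days = death, censor_days = cens
  )
}

#' Generate noisy SLD trajectories on the visit schedule
#'
#' For each subject, evaluates [ts_model()] at the scheduled visits, adds
#' additive normal residual error (truncated at 0 mm), and truncates the
#' series at the earliest of death, maximum follow-up, and (optionally) a
#' progression proxy: the first visit where the latent (noise-free) SLD
#' exceeds `1.2 * nadir + 5` mm, mimicking assessment until disease
#' progression. The proxy is applied to the latent curve, not the noisy
#' observation, because real progression calls require radiological
#' confirmation that a single noisy reading would not trigger. The
#' progression visit itself is kept.
#'
#' @param subjects data.frame with `subject_id`, `arm`, `ts0`, `kg`, `ks`,
#'   and `followup_weeks` (e.g. death time converted to weeks; `Inf` for
#'   none).
#' @param sigma2 additive residual variance, mm^2.
#' @param visit_weeks assessment schedule (weeks; must include 0).
#' @param dropout apply the progression-proxy truncation.
#' @return tumor-record data.frame in the [trial_dataset()] schema.
#' @export
generate_trajectories <- function(subjects, sigma2, visit_weeks = seq(0, 260, 8),
                                  dropout = TRUE) {
  stopifnot(0 %in% visit_weeks)
  sd_e <- sqrt(sigma2)
  rows <- lapply(seq_len(nrow(subjects)), function(i) {
    s <- subjects[i, ]
    tt <- visit_weeks[visit_weeks <= s$followup_weeks]
    if (!length(tt)) tt <- 0
    latent <- ts_model(tt, s$ts0, s$kg, s$ks)
    sld <- pmax(0, latent + rnorm(length(tt), 0, sd_e))
    if (dropout && length(tt) > 1) {
      prior_nadir <- c(latent[1], head(cummin(latent), -1))
      prog <- which(latent > 1.2 * prior_nadir + 5 & seq_along(tt) > 1)
      if (length(prog)) {
        keep <- seq_len(min(prog))
        tt <- tt[keep]; sld <- sld[keep]
      }
    }
    data.frame(subject_id = s$subject_id, arm = s$arm, time_weeks = tt,
               sld_mm = sld, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Configuration of the synthetic trial generator
#'
#' Defaults emulate the design of a two-arm ALK-positive first-line NSCLC
#' study: 143 evaluable subjects per arm plus 17 baseline-only subjects
#' (303 randomized, 286 evaluable), tumor assessments at baseline and every
#' 8 weeks until progression/death up to 260 weeks (5 years), TGI truth from
#' [default_tgi_truth()], OS truth from [default_os_truth()], uniform
#' censoring between 1 and 5 years.
#'
#' @param n_per_arm evaluable subjects per arm.
#' @param n_baseline_only extra subjects emitted with only a baseline scan
#'   (alternating arms); excluded by [filter_evaluable()].
#' @param visit_weeks assessment schedule.
#' @param tgi_truth,os_truth generating values.
#' @param covariates a [covariate_config()].
#' @param censor_bounds_days uniform study-duration bounds, days.
#' @param dropout apply the progression-proxy truncation of SLD series.
#' @param seed RNG seed.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_per_arm = 143, n_baseline_only = 17,
                             visit_weeks = seq(0, 260, 8),
                             tgi_truth = default_tgi_truth(),
                             os_truth = default_os_truth(),
                             covariates = covariate_config(),
                             censor_bounds_days = c(365, 1825),
                             dropout = TRUE, seed = 1L) {
  stopifnot(n_per_arm >= 1, all(diff(visit_weeks) > 0))
  structure(as.list(environment()), class = "generator_config")
}

#' Generate a complete virtual trial
#'
#' Draws covariates, individual TGI parameters (log-normal around the
#' arm-specific truths), OS outcomes from the AFT truth driven by the *true*
#' individual log KG, and noisy SLD trajectories truncated at
#' progression/death. Returns the observable [trial_dataset()] together with
#' the hidden per-subject truth (never written into the observable tables).
#'
#' @param cfg a [generator_config()].
#' @return object of class `virtual_trial`: `data` (a [trial_dataset()]),
#'   `truth` (data.frame with true `ts0`, `kg`, `ks`, `log_kg`, `mu`,
#'   `death_days`, `censor_days`), `config`.
#' @export
generate_trial <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  n_eval <- 2 * cfg$n_per_arm
  n <- n_eval + cfg$n_baseline_only
  arm <- c(rep(ARM_LEVELS, each = cfg$n_per_arm),
           rep_len(ARM_LEVELS, cfg$n_baseline_only))
  ids <- sprintf("S%04d", seq_len(n))
  cov <- sample_covariates(n, cfg$covariates, ids)
  par <- sample_tgi_params(arm, cfg$tgi_truth)
  cov$baseline_sld <- par$ts0
  design <- os_design(cov, setNames(par$log_kg, ids))
  osim <- generate_os(design, cfg$os_truth, cfg$censor_bounds_days)

  subj <- data.frame(subject_id = ids, arm = arm, ts0 = par$ts0, kg = par$kg,
                     ks = par$ks, stringsAsFactors = FALSE)
  subj$followup_weeks <- days_to_weeks(osim$death_days)
  baseline_only <- seq_len(n) > n_eval
  subj$followup_weeks[baseline_only] <- 0
  tumor <- generate_trajectories(subj, cfg$tgi_truth$sigma2, cfg$visit_weeks,
                                 dropout = cfg$dropout)

  truth <- cbind(subj[, c("subject_id", "arm", "ts0", "kg", "ks")],
                 log_kg = par$log_kg, eta_kg = par$eta_kg,
                 eta_ks = par$eta_ks, eta_ts0 = par$eta_ts0,
                 mu = osim$mu, death_days = osim$death_days,
                 censor_days = osim$censor_days)
  structure(list(
    data = trial_dataset(tumor, cov, osim$os),
    truth = truth,
    config = cfg
  ), class = "virtual_trial")
}

#' @export
print.virtual_trial <- function(x, ...) {
  cat("<virtual_trial> synthetic two-arm trial (seed ", x$config$seed, ")\n", sep = "")
  print(x$data)
  invisible(x)
}

#' Write a virtual trial to disk
#'
#' Writes the observable tables as the canonical `tumor.csv`,
#' `covariates.csv`, `os.csv` (via [write_trial()]) and the hidden truth as
#' `truth.json` — kept in a separate file so observed exports never leak
#' generating values.
#'
#' @param vt a [generate_trial()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_virtual_trial <- function(vt, dir) {
  stopifnot(inherits(vt, "virtual_trial"))
  write_trial(vt$data, dir)
  jsonlite::write_json(
    list(seed = vt$config$seed,
         tgi_truth = vt$config$tgi_truth,
         os_truth = vt$config$os_truth$coefficients,
         subjects = vt$truth),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
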